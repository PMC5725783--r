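ref <- bovineRhodopsin()

test_that("reference alignment maps positions through indels", {
  ## identity
  m <- alignToReference(ref, ref)
  expect_equal(m$ref, seq_len(nchar(ref)))
  expect_equal(m$query, seq_len(nchar(ref)))
  expect_true(all(diff(m$ref) > 0) && all(diff(m$query) > 0))

  ## residues 10-12 deleted in the query: offset 0 before, -3 after
  q <- paste0(substr(ref, 1, 9), substr(ref, 13, nchar(ref)))
  m2 <- alignToReference(q, ref)
  expect_equal(m2$query[m2$ref == 5], 5)
  expect_equal(m2$query[m2$ref == 20], 17)
  expect_false(any(m2$ref %in% 10:12))

  ## N-terminal 5-residue extension: reference position 1 -> query 6
  q3 <- paste0("GSGSG", ref)
  m3 <- alignToReference(q3, ref)
  expect_equal(m3$query[m3$ref == 1], 6)

  ## score floor flags non-opsin queries
  expect_error(alignToReference(strrep("PG", 150), ref, scoreFloor = 0),
               "below floor")
  expect_error(alignToReference("", ref), "empty")
})

test_that("tuning-site profiles extract residues, ambiguity and gaps", {
  fxV <- makeOpsinFixture("SWS1", residues = c(`86` = "V"))
  pV <- profileFromDNA(fxV$dna, "SWS1")
  expect_identical(pV@residues[["86"]], "V")

  fxHet <- makeOpsinFixture("SWS1", heterozygous = list(`86` = c("F", "V")))
  pH <- profileFromDNA(fxHet$dna, "SWS1")
  expect_identical(pH@residues[["86"]], c("F", "V"))

  fxDel <- makeOpsinFixture("LWS", deletions = 292L)
  pD <- profileFromDNA(fxDel$dna, "LWS")
  expect_true(is.na(pD@residues[["292"]]))
  expect_identical(pD@residues[["164"]], "S")

  ## a profile with no usable canonical site is rejected
  emptyMap <- data.frame(ref = 1:3, query = 1:3)
  expect_error(extractProfile("MNG", emptyMap, "LWS"), "unusable")
})

test_that("lambda-max predictions reproduce the published combinations", {
  lwsCases <- list(
    list(res = character(0), lambda = 560),
    list(res = c(`164` = "A"), lambda = 553),
    list(res = c(`164` = "A", `261` = "F"), lambda = 545),
    list(res = c(`164` = "A", `269` = "A"), lambda = 537))
  for (cs in lwsCases) {
    pred <- predictLambdaMax(
      profileFromDNA(makeOpsinFixture("LWS", cs$res)$dna, "LWS"))
    expect_equal(pred@lambda, cs$lambda)
    expect_equal(pred@provenance, "combination")
  }
  rh1Cases <- list(
    list(res = character(0), lambda = 500),
    list(res = c(`83` = "N", `299` = "A"), lambda = 493),
    list(res = c(`83` = "N", `292` = "S", `299` = "A"), lambda = 483))
  for (cs in rh1Cases) {
    pred <- predictLambdaMax(
      profileFromDNA(makeOpsinFixture("RH1", cs$res)$dna, "RH1"))
    expect_equal(pred@lambda, cs$lambda)
  }
  predF <- predictLambdaMax(
    profileFromDNA(makeOpsinFixture("SWS1")$dna, "SWS1"))
  expect_equal(predF@lambda, 360)
  expect_equal(predF@label, "UVS")
})

test_that("additive fallback sums the published shifts independent of order", {
  ## all five substitutions: 560 - (7 + 28 + 8 + 15 + 27) = 475
  prof <- profileFromDNA(makeOpsinFixture(
    "LWS", c(`164` = "A", `181` = "Y", `261` = "F", `269` = "A",
             `292` = "S"))$dna, "LWS")
  pred <- predictLambdaMax(prof)
  expect_equal(pred@lambda, 475)
  expect_equal(pred@provenance, "additive")

  ## single substitutions not covered by a combination entry
  predY <- predictLambdaMax(profileFromDNA(
    makeOpsinFixture("LWS", c(`181` = "Y"))$dna, "LWS"))
  expect_equal(predY@lambda, 560 - 28)
  predRH <- predictLambdaMax(profileFromDNA(
    makeOpsinFixture("RH1", c(`83` = "N"))$dna, "RH1"))
  expect_equal(predRH@lambda, 494)

  ## order independence: shifts commute because they are summed
  rules <- spectralRules("LWS")
  profAB <- new("TuningSiteProfile", opsinClass = "LWS",
                residues = list(`164` = "A", `181` = "Y", `261` = "Y",
                                `269` = "T", `292` = "A"))
  profBA <- new("TuningSiteProfile", opsinClass = "LWS",
                residues = list(`181` = "Y", `164` = "A", `261` = "Y",
                                `269` = "T", `292` = "A")[c(2, 1, 3, 4, 5)])
  expect_equal(predictLambdaMax(profAB, rules, additiveOnly = TRUE)@lambda,
               predictLambdaMax(profBA, rules, additiveOnly = TRUE)@lambda)

  ## combination entries take precedence over additive sums (553 vs 560-7)
  profS <- new("TuningSiteProfile", opsinClass = "LWS",
               residues = list(`164` = "A", `181` = "H", `261` = "Y",
                               `269` = "T", `292` = "A"))
  expect_equal(predictLambdaMax(profS, rules)@lambda, 553)
  expect_equal(predictLambdaMax(profS, rules, additiveOnly = TRUE)@lambda,
               553)  # additive happens to agree for the single substitution
  profSA <- new("TuningSiteProfile", opsinClass = "LWS",
                residues = list(`164` = "A", `181` = "H", `261` = "Y",
                                `269` = "A", `292` = "A"))
  expect_equal(predictLambdaMax(profSA, rules)@lambda, 537)
  expect_equal(predictLambdaMax(profSA, rules, additiveOnly = TRUE)@lambda,
               538)  # the printed combination deviates from additivity by 1
})

test_that("heterozygous, unknown and unscored sites are handled", {
  ## F/V heterozygote: two predictions, UV plus qualitative violet shift
  pred <- predictLambdaMax(profileFromDNA(
    makeOpsinFixture("SWS1", heterozygous = list(`86` = c("F", "V")))$dna,
    "SWS1"))
  expect_length(pred@lambda, 2L)
  expect_true(any(pred@label == "UVS" & pred@lambda == 360))
  expect_true(any(pred@label == "violet-shifted" & is.na(pred@lambda)))

  ## unknown site assumes base and is flagged
  profU <- new("TuningSiteProfile", opsinClass = "RH1",
               residues = list(`83` = "N", `292` = NA_character_,
                               `299` = "S"))
  predU <- predictLambdaMax(profU)
  expect_equal(predU@lambda, 494)
  expect_match(paste(predU@notes, collapse = " "), "292 unknown")

  ## unscored substitution contributes 0 and is flagged
  profX <- new("TuningSiteProfile", opsinClass = "RH1",
               residues = list(`83` = "D", `292` = "G", `299` = "S"))
  predX <- predictLambdaMax(profX)
  expect_equal(predX@lambda, 500)
  expect_match(paste(predX@notes, collapse = " "), "unscored")

  ## base profile always returns the base lambda exactly
  rules <- spectralRules("RH1")
  profB <- new("TuningSiteProfile", opsinClass = "RH1",
               residues = as.list(stats::setNames(rules@baseProfile,
                                                  names(rules@baseProfile))))
  expect_identical(predictLambdaMax(profB, rules)@lambda, 500)
  expect_error(predictLambdaMax(profB, spectralRules("LWS")), "match")
})

test_that("rule sets round-trip through the plain-text configuration", {
  tf <- tempfile(fileext = ".cfg")
  writeLines(c("# custom LWS rules", "class=LWS",
               "base=S164,H181,Y261,T269,A292", "base_lambda=560",
               "comb=S164A:553", "comb=S164A+T269A:537",
               "shift=S164A:-7", "shift=T269A:-15",
               "qual=S164G:odd-variant"), tf)
  rules <- readSpectralRules(tf)
  expect_equal(rules@baseLambda, 560)
  expect_equal(unname(rules@baseProfile[["164"]]), "S")
  expect_equal(rules@shifts[["T269A"]], -15)
  prof <- new("TuningSiteProfile", opsinClass = "LWS",
              residues = list(`164` = "A", `181` = "H", `261` = "Y",
                              `269` = "A", `292` = "A"))
  expect_equal(predictLambdaMax(prof, rules)@lambda, 537)
})

test_that("fixture truth matches the extracted profile end to end", {
  cases <- list(
    makeOpsinFixture("LWS", c(`164` = "A")),
    makeOpsinFixture("RH1", c(`83` = "N", `299` = "A")),
    makeOpsinFixture("SWS1", heterozygous = list(`86` = c("F", "V"))),
    makeOpsinFixture("SWS1", residues = c(`86` = "V"),
                     nTermExtension = "MGSSEEE", deletions = 200:206))
  for (fx in cases) {
    prof <- profileFromDNA(fx$dna, fx$truth$profile@opsinClass)
    for (s in names(fx$truth$profile@residues)) {
      tRes <- fx$truth$profile@residues[[s]]
      if (all(is.na(tRes))) next
      if (as.integer(s) %in% fx$truth$deletions) next
      expect_identical(prof@residues[[s]], tRes)
    }
    pred <- predictLambdaMax(prof)
    expect_equal(pred@lambda, fx$truth$prediction@lambda)
  }
})
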