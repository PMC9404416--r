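toy_phenotypes <- function() {
  tab <- data.frame(
    animal_id = c("A1", "A2", "A3", "A3", "A2"),
    herd = "H1",
    parity = c(1L, 1L, 2L, 3L, 2L),
    record_date = as.Date("2004-01-01") + 1:5,
    age_months = c(16, 17, 30, 43, 31),
    cg_code = c("CG1", "CG2", "CG1", "CG2", "CG1"),
    AFS = c(16, 17, NA, NA, NA),
    CFS = c(NA, NA, 60, 75, 90),
    stringsAsFactors = FALSE)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

toy_ainv <- function(ids = c("A1", "A2", "A3")) {
  ped <- pedigree(ids, rep(NA, length(ids)), rep(NA, length(ids)))
  a_inverse(ped)
}

test_that("design matrices absorb reference levels and keep full rank", {
  spec <- model_spec("AFS")
  mme <- build_mme(spec, toy_phenotypes(), toy_ainv())
  expect_equal(mme$n_records, 2L)   # only heifer rows carry AFS
  X <- mme$Xs[[1L]]
  expect_equal(dim(X), c(2L, 2L))   # intercept + one CG contrast
  expect_equal(qr(as.matrix(X))$rank, 2L)
  # every record maps to exactly one animal
  expect_equal(sort(unique(mme$animal)), 0:1)
})

test_that("repeated cow records share one permanent-environment level", {
  spec <- model_spec("CFS")
  mme <- build_mme(spec, toy_phenotypes(), toy_ainv())
  expect_equal(mme$n_records, 3L)
  expect_equal(mme$npe, 2L)
  lv <- mme$pe_level[mme$units$animal_id == "A3"]
  expect_equal(length(unique(lv)), 1L)  # both A3 lactations -> same level
  expect_true(all(mme$pe_trait))
})

test_that("the nine-trait model splits heifer and cow record classes", {
  sim <- small_sim()
  phen <- derive_phenotypes(sim$herd, min_size = 1L)
  ainv <- a_inverse(prune_pedigree(sim$ped, unique(phen$animal_id)))
  spec <- model_spec(analysis_sets()$joint)
  mme <- build_mme(spec, phen, ainv)
  expect_equal(ncol(mme$Y), 9L)
  expect_equal(length(unique(mme$trait_block)), 2L)
  hb <- mme$trait_block[match(c("AFS", "AFC", "SPCh"), mme$spec$traits)]
  cb <- mme$trait_block[match(analysis_sets()$cow, mme$spec$traits)]
  expect_equal(length(unique(hb)), 1L)
  expect_equal(length(unique(cb)), 1L)
  expect_false(hb[1L] == cb[1L])
  # heifer traits observed only on heifer units
  hrows <- mme$unit_block == hb[1L]
  expect_true(all(is.na(mme$Y[!hrows, "AFS"])))
  # the cow analysis set subsets to a single block
  mme_cow <- build_mme(model_spec(analysis_sets()$cow), phen, ainv)
  expect_equal(length(unique(mme_cow$trait_block)), 1L)
})

test_that("model building fails loudly on broken inputs", {
  spec <- model_spec("AFS")
  expect_error(build_mme(spec, toy_phenotypes(), toy_ainv(c("A1", "ZZ", "A3"))),
               "A2")
  tab <- toy_phenotypes()
  tab$AFS <- NULL
  expect_error(build_mme(spec, tab, toy_ainv()), "AFS")
  tab2 <- toy_phenotypes()
  tab2$cg_code[1L] <- NA
  expect_error(build_mme(spec, tab2, toy_ainv()), "contemporary group")
})

const_chain <- function(G, P, R, traits, cls, n = 5L) {
  t <- length(traits)
  rep_arr <- function(M) {
    a <- array(0, c(n, t, t))
    for (k in seq_len(n)) a[k, , ] <- M
    a
  }
  chain_samples(rep_arr(G), rep_arr(P), rep_arr(R), iteration = seq_len(n),
                traits = traits, animal_class = cls)
}

test_that("summary arithmetic matches hand-computed constant chains", {
  s <- summarize_chain(const_chain(matrix(1), matrix(1), matrix(2),
                                   "CFS", "cow"), burn_in = 0L)
  expect_equal(unname(s$h2$mean), 0.25)  # 1 / (1 + 1 + 2)
  expect_equal(unname(s$h2$sd), 0)

  G <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  s2 <- summarize_chain(const_chain(G, diag(0, 2), diag(1, 2),
                                    c("CFS", "DO"), c("cow", "cow")),
                        burn_in = 0L)
  expect_equal(s2$rg$mean[1, 2], 0.5)
  # phenotypic correlation from T = G0 + P0 + R0
  expect_equal(s2$rp$mean[1, 2], 0.5 / 2)
})

test_that("heritability ratios are averaged per iteration, not re-formed", {
  t <- 1L
  G <- array(c(0.2, 0.4), c(2, 1, 1))
  P <- array(0, c(2, 1, 1))
  R <- array(c(0.8, 0.6), c(2, 1, 1))
  ch <- chain_samples(G, P, R, iteration = 1:2, traits = "DO",
                      animal_class = "cow")
  s <- summarize_chain(ch, burn_in = 0L)
  expect_equal(unname(s$h2$mean), 0.3)             # mean of 0.2 and 0.4
  expect_equal(unname(s$h2$sd), stats::sd(c(0.2, 0.4)))
})

test_that("the pe variance enters the denominator only for cow traits", {
  G <- diag(c(1, 1)); P <- diag(c(1, 1)); R <- diag(c(2, 2))
  s <- summarize_chain(const_chain(G, P, R, c("AFS", "CFS"),
                                   c("heifer", "cow")), burn_in = 0L)
  expect_equal(unname(s$h2$mean), c(1 / 3, 1 / 4))
})

test_that("summaries refuse an empty post-burn-in window", {
  ch <- const_chain(matrix(1), matrix(0), matrix(1), "AFS", "heifer")
  expect_error(summarize_chain(ch, burn_in = 100L), "burn-in")
})

test_that("Geweke scores are calibrated under the null", {
  set.seed(81)
  flags <- vapply(seq_len(100L), function(r) {
    x <- rnorm(1000)
    ch <- chain_samples(array(x, c(1000, 1, 1)), array(0, c(1000, 1, 1)),
                        array(1, c(1000, 1, 1)), iteration = seq_len(1000),
                        traits = "DO", animal_class = "cow")
    abs(diagnostics(ch)$geweke_z[1L]) < 2
  }, TRUE)
  expect_gte(mean(flags), 0.95)
})

test_that("an injected mean shift is flagged and iid chains keep their length as ESS", {
  set.seed(82)
  x <- c(rnorm(200), rnorm(200, 3))
  ch <- chain_samples(array(x, c(400, 1, 1)), array(0, c(400, 1, 1)),
                      array(1, c(400, 1, 1)), iteration = seq_len(400),
                      traits = "DO", animal_class = "cow")
  d <- diagnostics(ch)
  expect_true(d$flagged[d$component == "G0"])

  x2 <- rnorm(2000)
  ch2 <- chain_samples(array(x2, c(2000, 1, 1)), array(0, c(2000, 1, 1)),
                       array(1, c(2000, 1, 1)), iteration = seq_len(2000),
                       traits = "DO", animal_class = "cow")
  d2 <- diagnostics(ch2)
  expect_gt(d2$ess[d2$component == "G0"], 2000 * 0.8)
  expect_lt(d2$ess[d2$component == "G0"], 2000 * 1.2)
  # structural zeros and fixed scales are not reported
  expect_false("P0" %in% d2$component)
  # trace data round-trips
  path <- write_traces(d2, tempfile(fileext = ".csv"))
  tr <- utils::read.csv(path, check.names = FALSE)
  expect_equal(tr[["G0[DO,DO]"]], x2)
})
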