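test_that("simulated pedigrees have the promised generation structure", {
  cfg1 <- herd_sim_config(n_founders = 40, n_generations = 1)
  p1 <- simulate_pedigree(cfg1, seed = 1)
  expect_equal(nrow(p1), 40L)
  expect_true(all(is.na(p1$sire) & is.na(p1$dam)))

  cfg <- herd_sim_config(n_founders = 100, n_generations = 3, sire_pool = 5)
  ped <- simulate_pedigree(cfg, seed = 2)
  g1 <- ped[ped$generation == 1L, ]
  fam <- table(g1$sire)
  expect_lte(length(fam), 5L)               # sire pool bounds family count
  expect_equal(sum(fam), 100L)              # family sizes sum to the generation
  expect_true(all(ped$sire[ped$generation == 1L] %in%
                    ped$animal[ped$generation == 0L]))
})

test_that("half-sib families average the expected additive relationship", {
  cfg <- herd_sim_config(n_founders = 60, n_generations = 2, sire_pool = 3,
                         n_per_generation = 120)
  ped <- simulate_pedigree(cfg, seed = 4)
  A <- relationship_matrix(ped)$matrix
  g1 <- which(ped$generation == 1L)
  sires <- ped$sire[g1]
  rel <- c()
  for (s in unique(sires)) {
    fam <- g1[sires == s]
    if (length(fam) < 2L) next
    block <- A[fam, fam]
    rel <- c(rel, block[upper.tri(block)])
  }
  # half sibs share >= 0.25; occasional shared dams push the mean above
  expect_gt(mean(rel), 0.24)
  expect_lt(mean(rel), 0.40)
})

test_that("breeding values follow the pedigree covariance structure", {
  ped <- simulate_pedigree(herd_sim_config(n_founders = 50,
                                           n_generations = 2), seed = 1)
  expect_equal(unname(simulate_breeding_values(ped, matrix(0, 1, 1), seed = 1)),
               matrix(0, nrow(ped), 1))

  founders <- simulate_pedigree(herd_sim_config(n_founders = 10000,
                                                n_generations = 1), seed = 2)
  bv <- simulate_breeding_values(founders, matrix(1, 1, 1), seed = 3)
  expect_gt(stats::var(bv[, 1L]), 0.95)
  expect_lt(stats::var(bv[, 1L]), 1.05)

  # empirical covariance over replicates matches A on a fixed small pedigree
  ped20 <- simulate_pedigree(herd_sim_config(n_founders = 8,
                                             n_generations = 3,
                                             sire_pool = 2,
                                             n_per_generation = 6), seed = 5)
  A <- relationship_matrix(ped20)$matrix
  n <- nrow(ped20)
  acc <- matrix(0, n, n)
  nrep <- 600L
  for (r in seq_len(nrep)) {
    b <- simulate_breeding_values(ped20, matrix(1, 1, 1), seed = 10000 + r)
    acc <- acc + tcrossprod(b[, 1L])
  }
  acc <- acc / nrep
  expect_lt(mean(abs(acc - A)), 0.06)
  expect_lt(max(abs(acc - A)), 0.35)
})

test_that("model-level phenotypes decompose as promised", {
  ped <- simulate_pedigree(herd_sim_config(n_founders = 500,
                                           n_generations = 1), seed = 1)
  G0 <- matrix(0.3, 1, 1)
  bv <- simulate_breeding_values(ped, G0, seed = 2)
  spec <- model_spec("AFS")
  # no residual, no pe, no CG effect: phenotype equals the breeding value
  truth0 <- sim_truth(G0, R0 = matrix(0, 1, 1), bv = bv, traits = "AFS")
  phen0 <- simulate_phenotypes(ped, truth0, spec, n_cg = 5, cg_sd = 0, seed = 3)
  expect_equal(phen0$AFS[order(phen0$animal_id)],
               unname(bv[order(rownames(bv)), 1L]))

  # pooled variance decomposition over replicates recovers the target h2
  truth <- sim_truth(G0, R0 = matrix(0.7, 1, 1), bv = bv, traits = "AFS")
  tot <- gen <- 0
  nrep <- 200L
  for (r in seq_len(nrep)) {
    bvr <- simulate_breeding_values(ped, G0, seed = 100 + r)
    tr <- sim_truth(G0, R0 = matrix(0.7, 1, 1), bv = bvr, traits = "AFS")
    ph <- simulate_phenotypes(ped, tr, spec, n_cg = 5, cg_sd = 0, seed = 500 + r)
    tot <- tot + stats::var(ph$AFS)
    gen <- gen + stats::var(bvr[, 1L])
  }
  expect_lt(abs(gen / tot - 0.3), 0.02)
})

test_that("binary liabilities centred at zero split the categories evenly", {
  ped <- simulate_pedigree(herd_sim_config(n_founders = 10000,
                                           n_generations = 1), seed = 6)
  G0 <- matrix(0.25, 1, 1)
  bv <- simulate_breeding_values(ped, G0, seed = 7)
  spec <- model_spec("PD100d")
  truth <- sim_truth(G0, R0 = matrix(0.75, 1, 1), bv = bv, traits = "PD100d")
  phen <- simulate_phenotypes(ped, truth, spec, n_cg = 10, cg_sd = 0, seed = 8)
  frac <- mean(phen$PD100d == 2)
  expect_gt(frac, 0.47)
  expect_lt(frac, 0.53)
})

test_that("sure conception gives SPC = 1 and DO = CFS everywhere", {
  cfg <- herd_sim_config(n_founders = 60, n_generations = 2,
                         p_conception_heifer = 0.9999,
                         p_conception_cow = 0.9999, fertility_sd = 1e-6,
                         n_lactations = 2)
  sim <- simulate_service_records(simulate_pedigree(cfg, seed = 1), cfg, seed = 2)
  tr <- sim$truth
  spc <- tr$value[tr$trait == "SPC"]
  expect_true(length(spc) > 0 && all(spc == 1))
  wide <- merge(tr[tr$trait == "DO", c("animal_id", "parity", "value")],
                tr[tr$trait == "CFS", c("animal_id", "parity", "value")],
                by = c("animal_id", "parity"))
  expect_true(nrow(wide) > 0)
  expect_equal(wide$value.x, wide$value.y)
})

test_that("hopeless conception leaves heifers without calvings", {
  cfg <- herd_sim_config(n_founders = 60, n_generations = 2,
                         p_conception_heifer = 1e-6,
                         p_conception_cow = 1e-6, fertility_sd = 1e-6)
  sim <- simulate_service_records(simulate_pedigree(cfg, seed = 1), cfg, seed = 2)
  expect_equal(sum(sim$herd$events$event_type == "CALVING"), 0L)
  expect_false("AFC" %in% sim$truth$trait)
  expect_true("AFS" %in% sim$truth$trait)
  # every female used her full service allowance in the single episode
  counts <- table(sim$herd$events$animal_id[sim$herd$events$event_type == "SERVICE"])
  expect_true(all(counts == cfg$max_services))
})

test_that("the simulator is bitwise reproducible under a fixed seed", {
  cfg <- herd_sim_config(n_founders = 50, n_generations = 2)
  p1 <- simulate_pedigree(cfg, seed = 9)
  p2 <- simulate_pedigree(cfg, seed = 9)
  expect_identical(p1, p2)
  s1 <- simulate_service_records(p1, cfg, seed = 10)
  s2 <- simulate_service_records(p2, cfg, seed = 10)
  expect_identical(s1, s2)
  b1 <- simulate_breeding_values(p1, matrix(1, 1, 1), seed = 11)
  b2 <- simulate_breeding_values(p1, matrix(1, 1, 1), seed = 11)
  expect_identical(b1, b2)
})
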