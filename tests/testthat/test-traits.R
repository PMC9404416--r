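herd_from_rows <- function(rows) read_service_records(write_service_csv(rows))

test_that("season assignment follows the October-March summer convention", {
  expect_equal(assign_season(as.Date("2005-10-01")), "summer")
  expect_equal(assign_season(as.Date("2005-04-30")), "winter")
  expect_equal(assign_season(as.Date(c("2005-03-31", "2005-09-30",
                                       "2005-12-15", "2005-01-02"))),
               c("summer", "winter", "summer", "summer"))
})

test_that("heifer traits derive from pre-calving services", {
  # first service 516 d after birth -> AFS = 516/30.4375 = 16.95 -> 17.0
  b <- as.Date("2000-01-01")
  sv <- b + c(516L, 537L, 558L)
  calv <- sv[3L] + 280L
  rows <- rbind(
    service_row("H1A", "SERVICE", format(sv[1L]), "failure"),
    service_row("H1A", "SERVICE", format(sv[2L]), "failure"),
    service_row("H1A", "SERVICE", format(sv[3L]), "success"),
    service_row("H1A", "CALVING", format(calv), "1"))
  tab <- derive_traits(herd_from_rows(rows))
  h <- tab[tab$parity == 1L, ]
  expect_equal(h$AFS, 17.0)
  expect_equal(h$SPCh, 3)
  expect_equal(h$AFC, round(as.integer(calv - b) / 30.4375, 1))
  expect_equal(h$age_months, h$AFS)
})

test_that("an animal with no services and no calvings contributes no row", {
  rows <- rbind(
    service_row("C1", "SERVICE", "2002-03-01", "success"),
    service_row("C1", "CALVING", "2002-12-10", "1"),
    service_row("C9", "DIAGNOSIS", "2002-05-01", "open"))
  tab <- derive_traits(herd_from_rows(rows))
  expect_false("C9" %in% tab$animal_id)
  log <- attr(tab, "edit_log")
  expect_true(any(log$animal_id == "C9" & log$rule_violated == "no services"))
})

test_that("cow traits follow the interval and success definitions", {
  # calving 2020-01-01, first service 2020-03-31 -> CFS = 90 days
  rows <- rbind(
    service_row("C2", "SERVICE", "2019-03-20", "success"),
    service_row("C2", "CALVING", "2020-01-01", "1"),
    service_row("C2", "SERVICE", "2020-03-31", "success"),
    service_row("C2", "DIAGNOSIS", "2020-05-12", "pregnant"))
  tab <- derive_traits(herd_from_rows(rows))
  cw <- tab[tab$parity == 2L, ]
  expect_equal(cw$CFS, 90)
  # services at 60, 81, 102 d post-calving, conception at the third
  calv <- as.Date("2020-01-01")
  rows <- rbind(
    service_row("C3", "SERVICE", "2019-03-20", "success"),
    service_row("C3", "CALVING", format(calv), "1"),
    service_row("C3", "SERVICE", format(calv + 60L), "failure"),
    service_row("C3", "SERVICE", format(calv + 81L), "failure"),
    service_row("C3", "SERVICE", format(calv + 102L), "success"),
    service_row("C3", "CALVING", format(calv + 102L + 280L), "2"))
  tab <- derive_traits(herd_from_rows(rows))
  cw <- tab[tab$animal_id == "C3" & tab$parity == 2L, ]
  expect_equal(cw$SPC, 3)
  expect_equal(cw$DO, 102)
  expect_equal(cw$FS80d, 2)   # served by day 80: yes
  expect_equal(cw$PD100d, 1)  # pregnant by day 100: no
  expect_equal(cw$PD200d, 2)  # pregnant by day 200: yes
})

test_that("conception needs a diagnosis or a calving in the gestation window", {
  calv <- as.Date("2020-01-01")
  # next calving 310 d after the last service: outside 260-302, no diagnosis
  rows <- rbind(
    service_row("C4", "SERVICE", "2019-03-20", "success"),
    service_row("C4", "CALVING", format(calv), "1"),
    service_row("C4", "SERVICE", format(calv + 70L), "unknown"),
    service_row("C4", "CALVING", format(calv + 70L + 310L), "2"))
  tab <- derive_traits(herd_from_rows(rows))
  cw <- tab[tab$animal_id == "C4" & tab$parity == 2L, ]
  expect_equal(cw$CFS, 70)
  expect_true(is.na(cw$DO))
  expect_true(is.na(cw$SPC))
})

test_that("edit rules remove out-of-bounds values and unknown-parent animals", {
  make_tab <- function(cfs_values) {
    rows <- do.call(rbind, lapply(seq_along(cfs_values), function(i) {
      calv <- as.Date("2002-02-19")  # 280 d after a first service at ~16 mo
      rbind(service_row(sprintf("C%02d", i), "SERVICE", "2001-05-15", "success"),
            service_row(sprintf("C%02d", i), "CALVING", format(calv), "1"),
            service_row(sprintf("C%02d", i), "SERVICE",
                        format(calv + cfs_values[i]), "failure"))
    }))
    derive_traits(herd_from_rows(rows))
  }
  tab <- make_tab(c(15L, 300L, 40L, 45L, 50L, 55L, 60L, 65L, 70L, 75L))
  cows <- tab[tab$parity == 2L, ]
  expect_equal(nrow(cows), 10L)
  edited <- apply_edits(tab)
  ecows <- edited[edited$parity == 2L, ]
  expect_equal(nrow(ecows), 8L)  # CFS 15 and 300 rows fall away entirely
  log <- attr(edited, "edit_log")
  expect_equal(sum(log$trait == "CFS"), 2L)
  expect_true(all(ecows$CFS >= 21 & ecows$CFS <= 250))
  # an in-bounds table passes through unchanged
  tab2 <- make_tab(c(40L, 50L, 60L))
  before <- attr(tab2, "edit_log")
  edited2 <- apply_edits(tab2)
  expect_equal(as.data.frame(edited2), as.data.frame(tab2))
  expect_equal(nrow(attr(edited2, "edit_log")), nrow(before))
})

test_that("DO outside 21-435 is excluded and its success traits cascade", {
  calv <- as.Date("2002-02-19")
  rows <- rbind(
    service_row("C5", "SERVICE", "2001-05-15", "success"),
    service_row("C5", "CALVING", format(calv), "1"),
    service_row("C5", "SERVICE", format(calv + 436L), "success"),
    service_row("C5", "DIAGNOSIS", format(calv + 480L), "pregnant"))
  tab <- derive_traits(herd_from_rows(rows))
  cw <- tab[tab$parity == 2L, ]
  expect_equal(cw$DO, 436)
  edited <- apply_edits(tab)
  log <- attr(edited, "edit_log")
  expect_true(any(log$trait == "DO" & log$raw_value == 436))
  expect_true(any(log$trait == "PD100d" &
                    log$rule_violated == "derived from excluded DO"))
  expect_true(any(log$trait == "FS80d" &
                    log$rule_violated == "derived from excluded CFS"))
  # the cow row survives only through its in-bounds services-per-conception
  cw5 <- edited[edited$parity == 2L & edited$animal_id == "C5", ]
  expect_equal(cw5$SPC, 1)
  expect_true(all(is.na(c(cw5$CFS, cw5$DO, cw5$FS80d, cw5$PD100d, cw5$PD200d))))
})

test_that("rows of animals with unknown parents are removed entirely", {
  rows <- rbind(
    service_row("K1", "SERVICE", "2001-06-01", "success", sire = "0"),
    service_row("K1", "CALVING", "2002-03-10", "1", sire = "0"),
    service_row("K2", "SERVICE", "2001-06-01", "success"),
    service_row("K2", "CALVING", "2002-03-10", "1"))
  herd <- herd_from_rows(rows)
  tab <- apply_edits(derive_traits(herd), parents = herd$animals)
  expect_false("K1" %in% tab$animal_id)
  expect_true("K2" %in% tab$animal_id)
  log <- attr(tab, "edit_log")
  expect_true(any(log$animal_id == "K1" & log$rule_violated == "unknown parent"))
})

test_that("contemporary groups combine herd, year and season of the right date", {
  tab <- data.frame(animal_id = c("A", "B"), herd = c("H1", "H2"),
                    parity = c(1L, 2L),
                    record_date = as.Date(c("2005-11-02", "2006-06-10")),
                    age_months = c(15, 30), AFS = c(15, NA), CFS = c(NA, 60),
                    stringsAsFactors = FALSE)
  class(tab) <- c("phenotype_table", "data.frame")
  out <- build_contemporary_groups(tab, min_size = 1L)
  expect_equal(out$cg_code, c("H1-2005-summer", "H2-2006-winter"))
})

test_that("contemporary groups below the minimum size are dropped and logged", {
  # 20 heifer rows: 18 in one November group, 2 in a lone June group
  n <- 20L
  dates <- as.Date(c(rep("2005-11-15", 18L), rep("2005-06-15", 2L)))
  tab <- data.frame(animal_id = sprintf("A%02d", seq_len(n)), herd = "H1",
                    parity = 1L, record_date = dates, age_months = 15,
                    AFS = rnorm(n, 17, 1), stringsAsFactors = FALSE)
  class(tab) <- c("phenotype_table", "data.frame")
  out <- build_contemporary_groups(tab, min_size = 3L)
  expect_equal(nrow(out), 18L)
  log <- attr(out, "edit_log")
  expect_equal(sum(log$rule_violated == "contemporary group below minimum size"), 2L)
  expect_true(all(out$cg_code == "H1-2005-summer"))
})

test_that("derived traits respect their interlocking definitions", {
  sim <- small_sim()
  tab <- derive_traits(sim$herd)
  cows <- tab[tab$parity > 1L, ]
  both <- !is.na(cows$CFS) & !is.na(cows$DO)
  expect_true(any(both))
  expect_true(all(cows$DO[both] >= cows$CFS[both]))
  expect_true(all(cows$SPC[!is.na(cows$SPC)] >= 1))
  expect_equal(cows$DO[both] == cows$CFS[both], cows$SPC[both] == 1)
  nest <- !is.na(cows$PD100d) & !is.na(cows$PD200d)
  expect_true(all(cows$PD200d[nest][cows$PD100d[nest] == 2] == 2))
  expect_true(all(tab$FS80d[!is.na(tab$FS80d)] %in% c(1, 2)))
})

test_that("derivation is deterministic", {
  sim <- small_sim()
  t1 <- derive_phenotypes(sim$herd)
  t2 <- derive_phenotypes(sim$herd)
  expect_identical(t1, t2)
})

test_that("derived values equal the simulator's truth ledger exactly", {
  sim <- small_sim()
  tab <- derive_traits(sim$herd)
  truth <- sim$truth
  long <- NULL
  for (tr in trait_specs()$name) {
    v <- tab[[tr]]
    keep <- !is.na(v)
    long <- rbind(long, data.frame(animal_id = tab$animal_id[keep],
                                   parity = tab$parity[keep], trait = tr,
                                   derived = v[keep], stringsAsFactors = FALSE))
  }
  m <- merge(truth, long, by = c("animal_id", "parity", "trait"), all = TRUE)
  expect_equal(nrow(m), nrow(truth))      # nothing derived beyond the ledger
  expect_true(all(!is.na(m$derived)))     # everything in the ledger derived
  expect_equal(m$derived, m$value)        # and equal, exactly
})
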