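# Shared fixtures, all built in code at test time.

# write a service-record CSV from a data frame of event rows
write_service_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

service_row <- function(animal_id, event_type, event_date, event_value,
                        herd = "H1", birth_date = "2000-01-01",
                        sire = "S1", dam = "D1") {
  data.frame(animal_id = animal_id, herd = herd, birth_date = birth_date,
             sire = sire, dam = dam, event_type = event_type,
             event_date = event_date, event_value = event_value,
             stringsAsFactors = FALSE)
}

# small simulated herd shared by io/trait tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- herd_sim_config(n_founders = 60, n_generations = 3, sire_pool = 5,
                             n_lactations = 2)
      ped <- simulate_pedigree(cfg, seed = 42)
      cache <<- c(list(ped = ped, cfg = cfg),
                  simulate_service_records(ped, cfg, seed = 43))
    }
    cache
  }
})

# phenotypes simulated under the estimation model for recovery checks
model_sim <- function(traits, G0, R0, P0 = NULL, n_founders = 400,
                      sire_pool = 40, n_records = 1L, n_cg = 30,
                      cg_sd = 0.5, seed = 1L) {
  cfg <- herd_sim_config(n_founders = n_founders, n_generations = 3,
                         sire_pool = sire_pool)
  ped <- simulate_pedigree(cfg, seed = seed)
  bv <- simulate_breeding_values(ped, G0, seed = seed + 1L)
  spec <- model_spec(traits)
  truth <- sim_truth(G0, P0 = P0, R0 = R0, bv = bv, traits = traits)
  phenotyped <- ped$animal[(n_founders + 1L):nrow(ped)]
  phen <- simulate_phenotypes(ped, truth, spec, phenotyped = phenotyped,
                              n_records = n_records, n_cg = n_cg,
                              cg_sd = cg_sd, seed = seed + 2L)
  list(ped = ped, spec = spec, phen = phen, ainv = a_inverse(ped),
       truth = truth)
}

# random pedigree for algebra stress tests: founders plus random matings
random_pedigree <- function(n, n_founders = max(10L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  animal <- sprintf("R%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq((n_founders + 1L), n)) {
    pa <- sample.int(i - 1L, 2L)
    sire[i] <- animal[pa[1L]]
    dam[i] <- animal[pa[2L]]
  }
  pedigree(animal, sire, dam,
           as.Date("2000-01-01") + seq_len(n))
}
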