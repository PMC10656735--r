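# Fixtures are generated in code, once per test run, and cached here.
.fixture_env <- new.env(parent = emptyenv())

# Small reference database (2 phyla x 1 x 1 x 2 x 2 = 8 leaves) for fast
# unit tests of search / classify / chimera.
small_db <- function() {
  if (is.null(.fixture_env$small)) {
    set.seed(101)
    ref <- make_reference_db(synth_config(
      n_phyla = 2L, classes_per_phylum = 1L, orders_per_class = 1L,
      families_per_order = 2L, genera_per_family = 2L))
    .fixture_env$small <- ref
  }
  .fixture_env$small
}

# Mid-size database (16 leaves) for the chimera sensitivity suite.
chimera_db <- function() {
  if (is.null(.fixture_env$chim)) {
    set.seed(202)
    ref <- make_reference_db(synth_config(
      n_phyla = 4L, classes_per_phylum = 1L, orders_per_class = 1L,
      families_per_order = 2L, genera_per_family = 2L))
    .fixture_env$chim <- ref
  }
  .fixture_env$chim
}

# Full synthetic community (seed 42), simulated once into a session tempdir.
sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    dir <- file.path(tempdir(), "mdmtriage_sim")
    truth <- simulate_community(dir, seed = 42L)
    .fixture_env$sim <- list(dir = dir, truth = truth)
  }
  .fixture_env$sim
}

# One pipeline run over the simulated community, cached.
sim_run <- function() {
  if (is.null(.fixture_env$run)) {
    fx <- sim_fixture()
    out <- file.path(tempdir(), "mdmtriage_run1")
    summary <- suppressWarnings(run_all(fx$dir, out))
    .fixture_env$run <- list(dir = out, summary = summary)
  }
  .fixture_env$run
}

read_out <- function(run, f) read.delim(file.path(run$dir, f),
                                        stringsAsFactors = FALSE)
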