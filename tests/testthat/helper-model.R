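# Lazily-built shared fixtures: a small training cohort and a trained MLP,
# reused by the pipeline and acceptance tests to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

get_training_fixture <- function() {
  if (is.null(.fixture_env$fixture)) {
    cohort <- periportal::generate_cohort(
      6, seed = 11L, grades = c(0L, 2L, 4L, 1L, 3L, 4L))
    cfg <- periportal::pipeline_config()
    tables <- list()
    results <- list()
    for (i in seq_along(cohort)) {
      res <- periportal::run_scene_pipeline(cohort[[i]]$scene, config = cfg)
      ft <- periportal::label_regions_by_truth(res, cohort[[i]]$truth)
      ft$scene <- i
      results[[i]] <- res
      tables[[i]] <- ft
    }
    all_ft <- do.call(rbind, tables)
    tr <- all_ft[all_ft$kind == "protruding", ]
    model <- periportal::train_mlp(tr, as.integer(tr$truth_infiltrated),
                                   w = 3, seed = 11L)
    .fixture_env$fixture <- list(cohort = cohort, results = results,
                                 features = all_ft, model = model)
  }
  .fixture_env$fixture
}
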