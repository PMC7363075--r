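# Shared end-to-end fixture: one desk-scale three-stage study, trained and
# evaluated once per test run.  Problem sizes: 100 phantoms at 24x96x96,
# 50% stroke, split 50/10/40, reduced model widths and epochs (CPU scale).

e2e_config <- function(seed = 20260101L) {
  pipeline_config(
    seed = seed, desk = TRUE,
    cavity = cavity_config(desk = TRUE, epochs = 6L),
    proposal = proposal_config(desk = TRUE, epochs = 6L),
    patch = patch_config(desk = TRUE, epochs = 5L),
    n_per_lesion_train = 12L)
}

e2e_fixture <- function() {
  memo("e2e", {
    config <- e2e_config()
    co <- generate_cohort(100, 0.5, seed = config$seed,
                          split_fractions = c(train = 0.5, val = 0.1,
                                              test = 0.4))
    models <- run_training(co$samples, co$cohort, config)
    test <- co$samples[co$cohort$split == "test"]
    eval_full <- evaluate_cohort(models, test)
    # any-surviving-proposal ablation, from the recorded lesion counts
    auc_prop_only <- roc_auc(as.numeric(eval_full$predictions$n_lesions > 0),
                             eval_full$predictions$label)$auc
    sens <- proposal_sensitivity(
      models, Filter(function(s) s$record$label == 1, test))
    list(cohort = co$cohort, models = models, eval = eval_full,
         auc_proposal_only = auc_prop_only, sensitivity = sens$sensitivity,
         n_lesions = sens$n_lesions)
  })
}
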