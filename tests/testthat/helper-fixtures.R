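# Shared fixtures, built lazily and cached for the whole test run. The heavy
# ones (tensorized dataset, cross-validated trainings, the revision cycle)
# are used by several test files; computing them once keeps the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# demo study conditions for the learning experiments: 10 subjects, 21-s
# recordings at 256 Hz => ~400 labelled 1-s segments, with the
# well-separated artifact menu (the learning-sanity precondition)
demo_sim_config <- function(seed = 7) {
  sim_config(n_subjects = 10, duration_s = 21, sr = 256,
             artifact_menu = separable_artifact_menu(), seed = seed)
}

demo_train_config <- function(seed = 11) {
  train_config(arch = demo_arch_spec(), epochs_cv = 10,
               lr = 0.02, batch_size = 8, t0 = 150, seed = seed)
}

get_demo_data <- function() {
  fixture("demo_data", function() {
    cfg <- demo_sim_config()
    fs <- design_bandpass(cfg$sr)
    recs <- lapply(generate_dataset(cfg), preprocess_recording, fs = fs)
    sd <- segment_dataset(recs)
    tz <- tensorize_dataset(recs, sd$segments)
    list(cfg = cfg, recordings = recs, dataset = sd,
         segments = sd$segments, tensors = tz$tensors)
  })
}

get_fold_plan <- function() {
  fixture("fold_plan", function() {
    make_folds(unique(get_demo_data()$segments$subject_id), k = 5, seed = 11)
  })
}

get_cv_result <- function() {
  fixture("cv_result", function() {
    d <- get_demo_data()
    train_cv(d$tensors, d$segments, get_fold_plan(), demo_train_config())
  })
}

get_shuffled_cv_result <- function() {
  fixture("shuffled_cv_result", function() {
    d <- get_demo_data()
    seg <- d$segments
    seg$label <- with_seed(4242, sample(seg$label))
    train_cv(d$tensors, seg, get_fold_plan(), demo_train_config())
  })
}

# revision experiment: corrupt 10% of the gold labels, run the
# train -> select -> re-annotate -> merge -> retrain cycle with perfect raters
get_revision_result <- function() {
  fixture("revision_result", function() {
    d <- get_demo_data()
    corr <- corrupt_labels(d$segments, fraction = 0.1, seed = 19)
    truth <- stats::setNames(d$segments$label, d$segments$segment_id)
    rater_fn <- function(cand) {
      dec <- simulate_raters(truth[cand$segment_id],
                             rater_model(p_agree_true = 1, seed = 5))
      data.frame(segment_id = cand$segment_id,
                 d1 = dec$rater1, d2 = dec$rater2,
                 stringsAsFactors = FALSE)
    }
    cyc <- revision_cycle(d$tensors, corr$segments, demo_train_config(),
                          revision_config(), rater_fn, epochs = 10)
    list(cycle = cyc, corrupted = corr, truth = truth)
  })
}
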