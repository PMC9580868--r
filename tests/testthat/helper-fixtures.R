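# Shared fixtures, built once per test run and memoised: the standard
# phantoms and the trained models / probability maps the end-to-end and
# acceptance tests score.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# phantom + ground truth for a standard fixture
fixture_phantom <- function(name) {
  memo(paste0("phantom_", name), generate_phantom(standard_fixtures()[[name]]))
}

# strokes -> training table for a standard fixture
fixture_training <- function(name, n_strokes = 2L, stroke_seed = 0L) {
  memo(sprintf("train_%s_%d_%d", name, n_strokes, stroke_seed), {
    ph <- fixture_phantom(name)
    ann <- simulate_strokes(ph$gt, n_strokes, n_strokes, radius = 1,
                            seed = stroke_seed)
    fm <- compute_features_at(ph$volume, live_tags(ann)$voxel_id)
    tt <- training_table(ann, fm)
    list(ann = ann, tt = tt)
  })
}

# RFC trained on a standard fixture + its dense probability map
fixture_rfc_run <- function(name, n_strokes = 2L, stroke_seed = 0L,
                            train_seed = 0L) {
  memo(sprintf("rfc_%s_%d_%d_%d", name, n_strokes, stroke_seed, train_seed), {
    ph <- fixture_phantom(name)
    tr <- fixture_training(name, n_strokes, stroke_seed)
    model <- train_classifier(classifier_spec("rfc", seed = train_seed),
                              tr$tt$x, tr$tt$y)
    pm <- infer_volume(model, ph$volume)
    list(model = model, pm = pm, ann = tr$ann, tt = tr$tt,
         dice = dice(pm, ph$gt), rmse = rmse(pm, ph$gt))
  })
}

# small linearly separable training set over the full 56-feature schema
separable_clusters <- function(n_per_class = 50L, p = 5L, seed = 0L,
                               shift = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, 0), n_per_class),
             matrix(rnorm(n_per_class * p, shift), n_per_class))
  colnames(x) <- paste0("F", seq_len(p))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}
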