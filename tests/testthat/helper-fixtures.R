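# Memoized fixtures shared across test files; everything is generated in code
# under fixed seeds, so the suite needs no stored data.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small separable channel stacks (500 samples): shockable-like content at
# 4 Hz, non-shockable-like at 12 Hz, with the SH/NSH side channels carrying
# the matching band. Cheap stand-ins for MVMD output in CNN/classifier tests.
make_tone_stack <- function(label, record_id, seed, n = 500, fs = 250) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  f <- if (label == 1) 4 else 12
  x <- sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + rnorm(n, 0, 0.1)
  sh <- if (label == 1) 0.8 * x else 0.1 * rnorm(n)
  nsh <- if (label == 1) 0.1 * rnorm(n) else 0.8 * x
  channel_stack(x, sh, nsh, label, record_id)
}

tone_stacks <- function(n_per_class = 24, n_records = 6) {
  fixture(sprintf("tone_%d_%d", n_per_class, n_records), function() {
    c(lapply(seq_len(n_per_class), function(i)
        make_tone_stack(1L, sprintf("tr%02d", (i %% n_records) + 1), 1000 + i)),
      lapply(seq_len(n_per_class), function(i)
        make_tone_stack(0L, sprintf("tr%02d", (i %% n_records) + 1), 2000 + i)))
  })
}

# A small trained network on the tone stacks, reused by feature/prediction
# and end-to-end tests.
tiny_trained_net <- function() {
  fixture("tiny_net", function() {
    cfg <- cnn_config(Ns = 2, Nd = 1, Lr = 0.005, Mo = 0.9, Re = 0.15,
                      input_len = 500)
    train_cnne(build_cnne(cfg, init_seed = 3), tone_stacks(),
               epochs = 6, seed = 3)
  })
}

# A complete small pipeline on 2-s synthetic segments: records -> segments ->
# preprocessing -> mode decomposition -> channel stacks -> trained extractor
# and boosting classifier. Used by end-to-end tests.
pipeline_fixture <- function() {
  fixture("pipeline2s", function() {
    params <- synth_params(seg_len_s = 2, seed = 77)
    recs <- gen_record_set(6, 8, 0.5, params)
    segs <- unlist(lapply(recs, segment_record, seg_len_s = 2),
                   recursive = FALSE)
    stacks <- segments_to_stacks(segs)
    cfg <- cnn_config(Ns = 2, Nd = 1, Lr = 0.005, Mo = 0.9, Re = 0.15,
                      input_len = 500)
    net <- train_cnne(build_cnne(cfg, init_seed = 7), stacks,
                      epochs = 6, seed = 7)
    bs <- train_classifier(classifier_spec("BS"),
                           extract_features(net, stacks),
                           vapply(stacks, function(s) s$label, integer(1)))
    list(params = params, net = net, bs = bs)
  })
}

# Gaussian 100-d feature fixture for the secondary classifiers: classes
# separated on the first five coordinates.
gaussian_features <- function(n_per_class = 100, p = 100, shift = 3,
                              seed = 99) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p), n_per_class))
  x[seq_len(n_per_class), 1:5] <- x[seq_len(n_per_class), 1:5] + shift
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}
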