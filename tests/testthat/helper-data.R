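rms_of <- function(w) sqrt(mean(w$samples^2))

# Fixtures built in code: single-condition localization datasets at the
# per-cell scale of the full design (48 double trials = 24 speaker pairs
# x 2 target/distractor assignments, plus one single-sound trial at each
# of the 17 unique elevations).

make_cell_trials <- function(fm = 120, dl = 0) {
  pairs <- double_sound_pairs()
  locs <- single_sound_locations()
  nd <- 2 * nrow(pairs)
  tibble::tibble(
    index = seq_len(nd + length(locs)),
    trial_type = c(rep("double", nd), rep("single", length(locs))),
    target_el = c(pairs$el_high, pairs$el_low, locs),
    distractor_el = c(pairs$el_low, pairs$el_high, rep(NA, length(locs))),
    fm_hz = c(rep(fm, nd), rep(NA, length(locs))),
    delta_l_db = c(rep(dl, nd), rep(NA, length(locs))))
}

cell_params <- function(w = 0.5, g = 1, b = 0, sigma_s = 8, sigma_d = 10,
                        fm = 120, dl = 0) {
  list(g = g, b = b, sigma_s = sigma_s,
       w_table = tibble::tibble(fm_hz = fm, delta_l_db = dl, w = w,
                                sigma_d = sigma_d))
}

# Minimal wa_posterior wrapper around given per-parameter sample vectors
# (single chain), for testing pooling and reporting in isolation.
make_posterior <- function(samples) {
  draws <- lapply(samples, function(x) matrix(x, ncol = 1))
  structure(list(draws = draws,
                 conditions = tibble::tibble(fm_hz = numeric(0),
                                             delta_l_db = numeric(0),
                                             w_param = character(0),
                                             sigma_param = character(0)),
                 n_chains = 1L, n_samples = length(samples[[1]]),
                 n_burn = 0L, seed = NA_integer_),
            class = "wa_posterior")
}
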