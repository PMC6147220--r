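# Factorial trial designs: double-sound localization, modulation-frequency
# discrimination, and modulation-phase discrimination, with seeded
# pseudo-random interleaving of single and double trials.
#
# Elevations use the double-pole convention (positive up), azimuth fixed
# at 0 (midsagittal plane). The 24 double-sound speaker configurations and
# their 17 unique elevations are a versioned config file
# (extdata/double_sound_pairs.csv), not code: two interleaved 15-degree
# lattices on the 5-degree cardinal-axis grid, separations tiling
# {15, 30, 45, 60, 75} degrees as evenly as possible (5/5/5/5/4 pairs).

DELTA_L_LEVELS <- c(-10, -5, 0, 5, 10)
FM_LEVELS <- c(5, 120, 2000)
BASE_LEVELS_DBA <- c(45, 50, 55, 60, 65)
SINGLE_KINDS <- c("GWN", "AM5", "AM120", "AM2000", "G5", "G120", "G2000")

#' The 24 double-sound speaker configurations
#'
#' Reads the versioned speaker-pair table: 24 midsagittal elevation pairs
#' in `[-45, 75]` degrees with separations in {15, 30, 45, 60, 75} and
#' exactly 17 unique elevations.
#'
#' @return A tibble with columns `el_low`, `el_high`, `separation_deg`.
#' @export
double_sound_pairs <- function() {
  path <- system.file("extdata", "double_sound_pairs.csv", package = "waloc")
  tibble::as_tibble(utils::read.csv(path))
}

#' The 17 single-sound elevations
#'
#' The unique elevations occurring in [double_sound_pairs()]; single
#' sounds are presented at every location also used in double trials.
#'
#' @return Sorted numeric vector of 17 elevations in degrees.
#' @export
single_sound_locations <- function() {
  p <- double_sound_pairs()
  sort(unique(c(p$el_low, p$el_high)))
}

new_trial_table <- function(trials, design_name, seed) {
  trials <- tibble::as_tibble(trials)
  attr(trials, "design_name") <- design_name
  attr(trials, "seed") <- as.integer(seed)
  class(trials) <- c("trial_table", class(trials))
  trials
}

trial_cols <- function(n) {
  tibble::tibble(
    index = integer(n), trial_type = character(n), sound_kind = character(n),
    target_el = numeric(n), distractor_el = rep(NA_real_, n),
    separation_deg = rep(NA_real_, n), delta_l_db = rep(NA_real_, n),
    fm_hz = rep(NA_real_, n), phase_rad = rep(NA_real_, n),
    am_level_dba = rep(NA_real_, n), gwn_level_dba = rep(NA_real_, n),
    base_level_dba = rep(NA_real_, n), duration_ms = numeric(n),
    variant = rep(NA_character_, n))
}

# Level pairs (L_am, L_gwn) on the calibrated 45-65 dBA grid whose
# difference equals delta_l; sampled uniformly over the feasible pairs.
feasible_level_pairs <- function(delta_l) {
  grid <- expand.grid(am = BASE_LEVELS_DBA, gwn = BASE_LEVELS_DBA)
  grid[grid$am - grid$gwn == delta_l, , drop = FALSE]
}

#' Build the double-sound localization trial table
#'
#' 720 double trials (5 level differences x 3 modulation frequencies x
#' 24 speaker configurations x 2 target/distractor assignments) plus 119
#' single trials (7 sound kinds x 17 locations), randomly interleaved
#' under `seed`. Per double trial the AM/GWN level pair is drawn uniformly
#' from the calibrated 45-65 dBA levels consistent with its level
#' difference.
#'
#' @param seed Integer seed governing level assignment and interleaving.
#' @return A `trial_table` tibble of 839 trials with attributes
#'   `design_name = "localization"` and `seed`.
#' @export
build_localization_trials <- function(seed = 1L) {
  pairs <- double_sound_pairs()
  grid <- expand.grid(delta_l = DELTA_L_LEVELS, fm = FM_LEVELS,
                      pair = seq_len(nrow(pairs)), assign = 1:2)
  nd <- nrow(grid)
  doubles <- trial_cols(nd)
  tgt_is_high <- grid$assign == 1
  doubles$trial_type <- "double"
  doubles$sound_kind <- "double"
  doubles$target_el <- ifelse(tgt_is_high, pairs$el_high[grid$pair],
                              pairs$el_low[grid$pair])
  doubles$distractor_el <- ifelse(tgt_is_high, pairs$el_low[grid$pair],
                                  pairs$el_high[grid$pair])
  doubles$separation_deg <- pairs$separation_deg[grid$pair]
  doubles$delta_l_db <- grid$delta_l
  doubles$fm_hz <- grid$fm
  doubles$phase_rad <- 0
  doubles$duration_ms <- 150

  locs <- single_sound_locations()
  sgrid <- expand.grid(kind = SINGLE_KINDS, el = locs,
                       stringsAsFactors = FALSE)
  ns <- nrow(sgrid)
  singles <- trial_cols(ns)
  singles$trial_type <- "single"
  singles$sound_kind <- sgrid$kind
  singles$target_el <- sgrid$el
  singles$fm_hz <- c(GWN = NA, AM5 = 5, AM120 = 120, AM2000 = 2000,
                     G5 = 5, G120 = 120, G2000 = 2000)[sgrid$kind]
  singles$phase_rad <- ifelse(sgrid$kind == "GWN", NA, 0)
  singles$duration_ms <- 150

  trials <- rbind(doubles, singles)
  trials <- withr::with_seed(as.integer(seed), {
    lv <- lapply(trials$delta_l_db, function(dl) {
      if (is.na(dl)) {
        l <- sample(BASE_LEVELS_DBA, 1)
        c(l, NA)
      } else {
        fp <- feasible_level_pairs(dl)
        row <- fp[sample.int(nrow(fp), 1), ]
        c(row$am, row$gwn)
      }
    })
    lv <- do.call(rbind, lv)
    trials$am_level_dba <- lv[, 1]
    trials$gwn_level_dba <- lv[, 2]
    trials
  })
  trials$base_level_dba <- rowMeans(trials[, c("am_level_dba", "gwn_level_dba")],
                                    na.rm = TRUE)
  trials$index <- seq_len(nrow(trials))
  interleave(new_trial_table(trials, "localization", seed),
             derive_seeds(seed, 1, salt = 11L))
}

#' Build the modulation-frequency discrimination trial table
#'
#' 120 double trials (2 target locations x 3 modulation frequencies x 20
#' repeats; AM target at +/-20 deg elevation, GWN distractor opposite,
#' phase 0, 400 ms, all levels 55 dBA) plus 60 single AM trials
#' (2 locations x 30 repeats, 10 per modulation frequency), interleaved
#' under `seed`.
#'
#' @param seed Integer seed.
#' @return A `trial_table` of 180 trials, `design_name = "discrim_freq"`.
#' @export
build_discrim_freq_trials <- function(seed = 1L) {
  dgrid <- expand.grid(el = c(20, -20), fm = FM_LEVELS, rep = 1:20)
  nd <- nrow(dgrid)
  doubles <- trial_cols(nd)
  doubles$trial_type <- "double"
  doubles$sound_kind <- "double"
  doubles$target_el <- dgrid$el
  doubles$distractor_el <- -dgrid$el
  doubles$separation_deg <- 40
  doubles$delta_l_db <- 0
  doubles$fm_hz <- dgrid$fm
  doubles$phase_rad <- 0

  sgrid <- expand.grid(el = c(20, -20), fm = FM_LEVELS, rep = 1:10)
  ns <- nrow(sgrid)
  singles <- trial_cols(ns)
  singles$trial_type <- "single"
  singles$sound_kind <- paste0("AM", sgrid$fm)
  singles$target_el <- sgrid$el
  singles$fm_hz <- sgrid$fm
  singles$phase_rad <- 0

  trials <- rbind(doubles, singles)
  trials$duration_ms <- 400
  trials$am_level_dba <- 55
  trials$gwn_level_dba <- ifelse(trials$trial_type == "double", 55, NA)
  trials$base_level_dba <- 55
  trials$index <- seq_len(nrow(trials))
  interleave(new_trial_table(trials, "discrim_freq", seed),
             derive_seeds(seed, 1, salt = 12L))
}

#' Build the modulation-phase discrimination trial table
#'
#' 480 trials of 5 Hz AM sounds: 160 singles (8 modulation phases x 2
#' locations x 10 repeats) and 320 doubles (8 phases x 2 locations x 2
#' sound-type assignments x 10 repeats). The sound-type factor records
#' which stimulus class occupies the upper speaker (`"am_up"` vs
#' `"am_down"`); the location factor is the AM target's elevation. All
#' sounds 400 ms at 55 dBA.
#'
#' @param seed Integer seed.
#' @return A `trial_table` of 480 trials, `design_name = "discrim_phase"`.
#' @export
build_discrim_phase_trials <- function(seed = 1L) {
  phases <- (0:7) * pi / 4
  dgrid <- expand.grid(phase = phases, el = c(20, -20), variant = 1:2,
                       rep = 1:10)
  nd <- nrow(dgrid)
  doubles <- trial_cols(nd)
  doubles$trial_type <- "double"
  doubles$sound_kind <- "double"
  doubles$target_el <- dgrid$el
  doubles$distractor_el <- -dgrid$el
  doubles$separation_deg <- 40
  doubles$delta_l_db <- 0
  doubles$fm_hz <- 5
  doubles$phase_rad <- dgrid$phase
  doubles$variant <- ifelse(xor(dgrid$variant == 1, dgrid$el < 0),
                            "am_up", "am_down")

  sgrid <- expand.grid(phase = phases, el = c(20, -20), rep = 1:10)
  ns <- nrow(sgrid)
  singles <- trial_cols(ns)
  singles$trial_type <- "single"
  singles$sound_kind <- "AM5"
  singles$target_el <- sgrid$el
  singles$fm_hz <- 5
  singles$phase_rad <- sgrid$phase

  trials <- rbind(doubles, singles)
  trials$duration_ms <- 400
  trials$am_level_dba <- 55
  trials$gwn_level_dba <- ifelse(trials$trial_type == "double", 55, NA)
  trials$base_level_dba <- 55
  trials$index <- seq_len(nrow(trials))
  interleave(new_trial_table(trials, "discrim_phase", seed),
             derive_seeds(seed, 1, salt = 13L))
}

#' Pseudo-randomly interleave trials
#'
#' Permutes the presentation order reproducibly under `seed`. Trial ids
#' (the `index` column) travel with their rows, so the trial multiset is
#' unchanged.
#'
#' @param trials A `trial_table` (or plain tibble of trials).
#' @param seed Integer permutation seed.
#' @return The permuted `trial_table`.
#' @export
interleave <- function(trials, seed) {
  perm <- withr::with_seed(as.integer(seed), sample.int(nrow(trials)))
  out <- trials[perm, ]
  attr(out, "design_name") <- attr(trials, "design_name")
  attr(out, "seed") <- attr(trials, "seed")
  class(out) <- class(trials)
  out
}

#' Write a trial table to CSV
#'
#' The design name and seed are stored as `#`-prefixed header lines, so
#' [read_trial_table()] round-trips losslessly.
#'
#' @param trials A `trial_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# design_name=%s", attr(trials, "design_name")), con)
  writeLines(sprintf("# seed=%d", attr(trials, "seed")), con)
  utils::write.table(as.data.frame(trials), con, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#'
#' @param path CSV path.
#' @return A `trial_table` with its `design_name` and `seed` attributes.
#' @export
read_trial_table <- function(path) {
  hdr <- readLines(path, n = 2)
  design_name <- sub("^# design_name=", "", hdr[1])
  seed <- as.integer(sub("^# seed=", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(variant = "character"))
  df$variant[df$variant == "NA" | df$variant == ""] <- NA_character_
  new_trial_table(tibble::as_tibble(df), design_name, seed)
}
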