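## Synthetic single-particle interferometry (SP-IRIS style) exports: one row
## per detected particle with its capture spot, diameter and per-channel
## fluorescence positivity, emulating the tables produced by tetraspanin
## microarray readers.

CAPTURE_SPOTS <- c("CD9", "CD63", "CD81", "CD41a", "IgG")
DETECTION_CHANNELS <- c("CD9", "CD63", "PSMA")

## Instrument reporting limits (nm); analysis applies the 50-200 nm window
## separately via filter_size_window().
INSTRUMENT_SIZE_RANGE <- c(30, 250)

#' Planted particle truth for the three patient groups
#'
#' One row per group x capture spot with the planted particle rate
#' (expected particles per subject chip), the planted modal 5-nm size bin
#' (labelled by its lower edge) and the planted detection-channel
#' positivity probabilities.  Defaults emulate plasma S-EV profiles from
#' benign hyperplasia (BPH), localised (LPCa) and advanced (AdvPCa)
#' prostate cancer: CD63+/CD81+ vesicles peaking in the 50-nm bin, CD9+
#' vesicles in the 55-nm bin, platelet-marker CD41a larger, a CD9-capture
#' excess in the advanced group and PSMA positivity rising with disease
#' stage.  IgG rows are the isotype-control background.
#'
#' @return an \code{ev_particle_truth} data.frame.
#' @export
particle_truth_patients <- function() {
  grid <- expand.grid(group = c("BPH", "LPCa", "AdvPCa"),
                      capture = CAPTURE_SPOTS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rate <- c(BPH.CD9 = 300, LPCa.CD9 = 380, AdvPCa.CD9 = 950,
            BPH.CD63 = 420, LPCa.CD63 = 520, AdvPCa.CD63 = 460,
            BPH.CD81 = 350, LPCa.CD81 = 500, AdvPCa.CD81 = 320,
            BPH.CD41a = 220, LPCa.CD41a = 260, AdvPCa.CD41a = 230,
            BPH.IgG = 25, LPCa.IgG = 25, AdvPCa.IgG = 25)
  mode <- c(BPH.CD9 = 55, LPCa.CD9 = 55, AdvPCa.CD9 = 55,
            BPH.CD63 = 50, LPCa.CD63 = 50, AdvPCa.CD63 = 50,
            BPH.CD81 = 50, LPCa.CD81 = 50, AdvPCa.CD81 = 50,
            BPH.CD41a = 55, LPCa.CD41a = 60, AdvPCa.CD41a = 60,
            BPH.IgG = 55, LPCa.IgG = 55, AdvPCa.IgG = 55)
  key <- paste(grid$group, grid$capture, sep = ".")
  psma <- ifelse(grid$capture == "IgG", 0.03,
                 c(BPH = 0.03, LPCa = 0.08, AdvPCa = 0.18)[grid$group])
  truth <- data.frame(
    grid,
    rate = unname(rate[key]),
    size_mode = unname(mode[key]),
    size_sd = 4,
    p_CD9 = ifelse(grid$capture == "IgG", 0.05,
                   ifelse(grid$capture == "CD9", 0.85, 0.40)),
    p_CD63 = ifelse(grid$capture == "IgG", 0.05,
                    ifelse(grid$capture == "CD63", 0.85, 0.35)),
    p_PSMA = psma,
    stringsAsFactors = FALSE)
  structure(truth, class = c("ev_particle_truth", "data.frame"))
}

#' Planted particle truth for culture treatment arms
#'
#' Treatment-arm version of \code{\link{particle_truth_patients}} for
#' conditioned-medium experiments (FBS, charcoal-stripped serum, and CSS
#' with DHT and/or enzalutamide).  DHT raises the CD63-capture rate and
#' shifts part of the CD9+ population from the 50-nm to the 55-nm bin;
#' PSMA-positivity drops under DHT relative to ENZ.
#'
#' @return an \code{ev_particle_truth} data.frame.
#' @export
particle_truth_treatment <- function() {
  arms <- c("FBS", "CSS", "CSS+DHT", "CSS+ENZ", "CSS+DHT+ENZ")
  spots <- c("CD9", "CD63", "CD81", "IgG")
  grid <- expand.grid(group = arms, capture = spots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dht <- grepl("DHT", grid$group)
  rate <- ifelse(grid$capture == "IgG", 25,
          ifelse(grid$capture == "CD63" & dht, 700,
          ifelse(grid$capture == "CD63", 380, 420)))
  mode <- ifelse(grid$capture == "CD9" & dht, 55, 50)
  psma <- ifelse(grid$capture == "IgG", 0.03, ifelse(dht, 0.05, 0.12))
  truth <- data.frame(
    grid, rate = rate, size_mode = mode, size_sd = 4,
    p_CD9 = ifelse(grid$capture == "IgG", 0.05,
                   ifelse(grid$capture == "CD9", 0.85, 0.40)),
    p_CD63 = ifelse(grid$capture == "IgG", 0.05,
                    ifelse(grid$capture == "CD63", 0.85, 0.35)),
    p_PSMA = psma,
    stringsAsFactors = FALSE)
  structure(truth, class = c("ev_particle_truth", "data.frame"))
}

validate_particle_truth <- function(truth) {
  stopifnot(is.data.frame(truth))
  p <- unlist(truth[c("p_CD9", "p_CD63", "p_PSMA")])
  if (any(p < 0 | p > 1)) stop("channel positivity probabilities not in [0,1]")
  if (any(truth$rate < 0)) stop("particle rates must be >= 0")
  sz <- truth$size_mode[truth$rate > 0]
  if (any(sz < 50 | sz > 200)) stop("size modes must lie in [50, 200] nm")
  invisible(truth)
}

#' Simulate per-subject particle tables
#'
#' For every subject and capture spot, the particle count is Poisson with a
#' per-subject lognormal scaling (shared across that subject's spots);
#' diameters are Normal around the planted modal bin midpoint
#' (\code{size_mode} + 2.5 nm for 5-nm bins) and clipped to the instrument
#' reporting range; channel positivity is independent Bernoulli per
#' channel.  IgG spots draw from the background-only rate.  Deterministic
#' per seed.
#'
#' @param truth an \code{ev_particle_truth} (see
#'   \code{\link{particle_truth_patients}}).
#' @param n_subjects named integer vector, group -> number of subjects;
#'   the default matches the plasma cohort sizes (BPH 10, LPCa 11,
#'   AdvPCa 15) when those groups are present.
#' @param seed integer seed.
#' @param subject_cv lognormal sdlog of the per-subject scaling factor.
#' @param dilution_factor reported dilution scaling (1 = counts as is).
#' @return an \code{ev_particle_table} data.frame: subject_id, group,
#'   capture, size_nm, ch_CD9, ch_CD63, ch_PSMA (0/1), dilution_factor.
#' @export
simulate_particles <- function(truth, n_subjects = NULL, seed = 1L,
                               subject_cv = 0.3, dilution_factor = 1) {
  validate_particle_truth(truth)
  groups <- unique(truth$group)
  if (is.null(n_subjects)) {
    n_subjects <- stats::setNames(
      ifelse(groups %in% c("BPH", "LPCa", "AdvPCa"),
             c(BPH = 10L, LPCa = 11L, AdvPCa = 15L)[groups], 5L), groups)
  }
  if (any(n_subjects < 1L)) stop("need >= 1 subject per group")
  with_seed(seed, {
    out <- list()
    for (g in groups) {
      tg <- truth[truth$group == g, ]
      for (s in seq_len(n_subjects[[g]])) {
        sid <- sprintf("%s_%02d", g, s)
        scale_s <- exp(stats::rnorm(1L, 0, subject_cv))
        for (r in seq_len(nrow(tg))) {
          n <- stats::rpois(1L, tg$rate[r] * scale_s)
          if (n == 0L) next
          size <- stats::rnorm(n, tg$size_mode[r] + 2.5, tg$size_sd[r])
          size <- pmin(pmax(size, INSTRUMENT_SIZE_RANGE[1L]),
                       INSTRUMENT_SIZE_RANGE[2L])
          out[[length(out) + 1L]] <- data.frame(
            subject_id = sid, group = g, capture = tg$capture[r],
            size_nm = round(size, 1L),
            ch_CD9 = stats::rbinom(n, 1L, tg$p_CD9[r]),
            ch_CD63 = stats::rbinom(n, 1L, tg$p_CD63[r]),
            ch_PSMA = stats::rbinom(n, 1L, tg$p_PSMA[r]),
            dilution_factor = dilution_factor,
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    class(tab) <- c("ev_particle_table", "data.frame")
    tab
  })
}

#' Write / read particle tables as CSV
#'
#' @param particles an \code{ev_particle_table}.
#' @param path CSV path.
#' @return the path (write) or the table (read).
#' @export
write_particle_csv <- function(particles, path) {
  utils::write.csv(as.data.frame(particles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_particle_csv
#' @export
read_particle_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("ev_particle_table", "data.frame")
  tab
}
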