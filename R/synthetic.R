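#' Generate a synthetic two-(or more-)modality dataset
#'
#' Gaussian class-conditional generator used to exercise every fusion stage
#' with known ground truth. Labels are Bernoulli(`balance`); modality `m`
#' consists of `S_m` signal features (unit-variance Gaussians whose class
#' means differ by `d_m`, in units of the noise sd) followed by
#' `P_m - S_m` pure-noise features, the whole modality multiplied by a global
#' scale factor to emulate scale heterogeneity between modalities. The
#' closed-form AUC of a single signal feature is `pnorm(d / sqrt(2))`
#' ([theoretical_auc()]), and of an optimal per-modality score
#' `pnorm(sqrt(S_m) * d_m / sqrt(2))` (independent features), which is what
#' calibration tests check.
#'
#' Signal structure:
#' * `"complementary"` — each modality carries an independent noisy copy of
#'   the class signal, so the joint optimal score beats each modality alone;
#' * `"redundant"` — one latent class-driven factor underlies the signal
#'   features of every modality (cross-modality correlated signal);
#' * `"one_noisy"` — all modalities after the first have their effect size
#'   forced to 0 (pure noise).
#'
#' @param N Sample count.
#' @param P Integer vector of per-modality feature counts.
#' @param S Integer vector of per-modality signal feature counts
#'   (`S_m <= P_m`).
#' @param effect Per-modality class-mean gap `d_m` (noise-sd units).
#' @param structure `"complementary"`, `"redundant"`, or `"one_noisy"`.
#' @param noise_sd Noise standard deviation (default 1).
#' @param balance Class-1 probability in (0, 1).
#' @param n_groups Number of patient groups (default: one per sample);
#'   samples are dealt to groups round-robin.
#' @param scales Per-modality global scale factors (default `1, 10, 100, ...`).
#' @param seed Integer seed; the same seed reproduces bit-identical matrices.
#' @return A `multimodal_dataset`.
#' @export
generate_multimodal <- function(N, P, S, effect,
                                structure = c("complementary", "redundant",
                                              "one_noisy"),
                                noise_sd = 1, balance = 0.5, n_groups = NULL,
                                scales = NULL, seed = 1) {
  structure <- match.arg(structure)
  M <- length(P)
  S <- rep_len(S, M); effect <- rep_len(effect, M)
  if (any(S > P)) stop_fusedr("Signal dims S_m cannot exceed P_m.", "config")
  if (any(effect < 0)) stop_fusedr("Effect sizes must be nonnegative.", "config")
  if (balance <= 0 || balance >= 1) stop_fusedr("`balance` must be in (0,1).",
                                                "config")
  if (structure == "one_noisy" && M > 1) effect[-1] <- 0
  if (is.null(scales)) scales <- 10^(seq_len(M) - 1)
  ids <- sprintf("s%04d", seq_len(N))
  withr::with_seed(seed, {
    y <- rbinom(N, 1, balance)
    if (length(unique(y)) < 2) {          # tiny-N guard: force both classes
      y[1] <- 0L; y[2] <- 1L
    }
    latent <- rnorm(N)                    # shared factor for "redundant"
    mods <- list()
    for (m in seq_len(M)) {
      X <- matrix(rnorm(N * P[m], sd = noise_sd), N, P[m])
      if (S[m] > 0 && effect[m] > 0) {
        shift <- effect[m] * noise_sd * y
        if (structure == "redundant") {
          # class-driven latent shared across modalities + feature noise
          base <- shift + noise_sd * latent
          X[, seq_len(S[m])] <- matrix(base, N, S[m]) +
            matrix(rnorm(N * S[m], sd = noise_sd), N, S[m])
        } else {
          X[, seq_len(S[m])] <- X[, seq_len(S[m]), drop = FALSE] + shift
        }
      }
      X <- X * scales[m]
      rownames(X) <- ids
      colnames(X) <- c(
        if (S[m] > 0) sprintf("sig%03d", seq_len(S[m])),
        if (P[m] > S[m]) sprintf("noise%03d", seq_len(P[m] - S[m]))
      )
      mods[[paste0("modality", m)]] <- X
    }
  })
  grp <- if (is.null(n_groups)) ids
         else sprintf("g%03d", 1L + (seq_len(N) - 1L) %% n_groups)
  labels <- data.frame(sample_id = ids, label = y, group = grp)
  suppressWarnings(multimodal_dataset(mods, labels))
}

#' Closed-form AUC of one Gaussian signal feature
#'
#' For a unit-variance Gaussian feature whose class means differ by `d`, the
#' ROC AUC is `pnorm(d / sqrt(2))` — the calibration target for the
#' synthetic generator.
#'
#' @param d Nonnegative class-mean gap in noise-sd units.
#' @return AUC in \[0.5, 1\).
#' @export
theoretical_auc <- function(d) {
  if (any(d < 0)) stop_fusedr("`d` must be nonnegative.", "parameter")
  pnorm(d / sqrt(2))
}

#' Synthetic fixtures emulating the three benchmark cohort regimes
#'
#' Shape-matched synthetic stand-ins for the three cohort regimes the
#' package's presets are aimed at (the real cohorts are consortium-held
#' clinical data):
#'
#' * `"alz_like"` — 77 samples x (327 + 146) features, both modalities
#'   moderately discriminative (MRI volumetry + plasma proteomics regime);
#' * `"bcr_like"` — 40 samples x (189 + 650) features, weak signal in a
#'   large noisy feature space (big-P-small-N recurrence-prediction regime);
#' * `"voxel_like"` — 3000 samples in 36 patient groups x (58 + 6) features,
#'   weak wide modality + strong narrow modality (per-voxel MRI + MRS
#'   regime).
#'
#' Effect sizes are this package's choices (the true ones are unknowable
#' from cohort summaries); only shapes and qualitative regimes are matched.
#'
#' @param regime `"alz_like"`, `"bcr_like"`, or `"voxel_like"`.
#' @param seed Integer seed.
#' @return A `multimodal_dataset`.
#' @export
make_fixture <- function(regime = c("alz_like", "bcr_like", "voxel_like"),
                         seed = 1) {
  if (!is.character(regime) || !regime[1] %in%
      c("alz_like", "bcr_like", "voxel_like")) {
    stop_fusedr(sprintf("Unknown regime '%s'.", regime[1]), "config")
  }
  regime <- regime[1]
  switch(
    regime,
    alz_like = generate_multimodal(
      N = 77, P = c(327, 146), S = c(12, 8), effect = c(0.8, 0.6),
      structure = "complementary", balance = 52 / 77, seed = seed),
    bcr_like = generate_multimodal(
      N = 40, P = c(189, 650), S = c(5, 5), effect = c(0.25, 0.2),
      structure = "complementary", balance = 0.5, seed = seed),
    voxel_like = generate_multimodal(
      N = 3000, P = c(58, 6), S = c(10, 3), effect = c(0.3, 1.0),
      structure = "complementary", balance = 0.5, n_groups = 36, seed = seed)
  )
}
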