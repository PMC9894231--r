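#' Configuration for the synthetic two-platform screen
#'
#' Defines a screen with `n_classes` planted mechanism classes of
#' `members_per_class` reference compounds each, `n_noise_perturbagens`
#' unannotated reference compounds with pure-noise profiles, and
#' `n_fractions` natural-product fractions (mixtures). Each class has a mean
#' Z-fingerprint of Euclidean norm `d` per platform, zeroed in platforms
#' where the class is invisible; members add i.i.d. Gaussian noise with sd
#' `noise_sd` (default `1/sqrt(3)`, the residual noise of a
#' triplicate-averaged unit-variance Z-score). A subset of classes drives
#' bioactive fractions: one bioactive compound per such class, each planted
#' in `fractions_per_bioactive` fractions, alongside 3-10 inert compounds
#' drawn from a shared pool.
#'
#' @param n_classes Number of planted classes (default 10).
#' @param members_per_class Reference compounds per class (default 8).
#' @param n_noise_perturbagens Unannotated noise compounds (default 80).
#' @param n_fractions Natural-product fractions (default 60).
#' @param features_a,features_b Feature counts of the two platforms
#'   (defaults 14 and 251, the gene-signature and cytological panels).
#' @param d Class effect size: Euclidean norm of the class mean fingerprint,
#'   in Z units (default 2).
#' @param platform_visibility Character vector (recycled over classes) of
#'   `"both"`, `"A"`, or `"B"`; default cycles through the three.
#' @param noise_sd Per-feature Gaussian noise sd (default `1/sqrt(3)`).
#' @param n_bioactive_classes Classes that drive bioactive fractions
#'   (default 5, capped at `n_classes`).
#' @param fractions_per_bioactive Fractions carrying each bioactive compound
#'   (default 4; must be >= 2 so every bioactive basket has a defined SNF
#'   score).
#' @param n_inert_compounds Size of the shared inert compound pool
#'   (default 40).
#' @param seed Mandatory RNG seed.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(n_classes = 10L, members_per_class = 8L,
                          n_noise_perturbagens = 80L, n_fractions = 60L,
                          features_a = 14L, features_b = 251L, d = 2,
                          platform_visibility = c("both", "A", "B"),
                          noise_sd = 1 / sqrt(3),
                          n_bioactive_classes = 5L,
                          fractions_per_bioactive = 4L,
                          n_inert_compounds = 40L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_classes < 1L || members_per_class < 1L || n_fractions < 1L ||
      features_a < 1L || features_b < 1L || n_inert_compounds < 1L)
    stop("counts must be positive")
  if (d < 0) stop("d must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (fractions_per_bioactive < 2L)
    stop("fractions_per_bioactive must be >= 2")
  n_bioactive_classes <- min(n_bioactive_classes, n_classes)
  if (n_bioactive_classes * fractions_per_bioactive > n_fractions)
    stop("not enough fractions to host the bioactive compounds")
  structure(list(n_classes = as.integer(n_classes),
                 members_per_class = as.integer(members_per_class),
                 n_noise_perturbagens = as.integer(n_noise_perturbagens),
                 n_fractions = as.integer(n_fractions),
                 features_a = as.integer(features_a),
                 features_b = as.integer(features_b), d = d,
                 platform_visibility =
                   rep_len(platform_visibility, n_classes),
                 noise_sd = noise_sd,
                 n_bioactive_classes = as.integer(n_bioactive_classes),
                 fractions_per_bioactive = as.integer(fractions_per_bioactive),
                 n_inert_compounds = as.integer(n_inert_compounds),
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Simulate a two-platform phenotypic screen with known ground truth
#'
#' @param cfg A [screen_config()].
#' @return List with `profile_a`, `profile_b` (`profile_matrix`, platforms
#'   `"FUSION"` and `"CP"`), `annotations` (`annotation_table`; fractions and
#'   noise compounds carry `"none"`), and `truth`: list with
#'   `perturbagen_class` (named vector over references),
#'   `class_visibility`, `fraction_compounds` (named list), `compounds`
#'   (data.frame `compound`, `class`, `bioactive`, `mz`, `rt`, `ccs`), and
#'   `bioactive_fractions` (named list class -> fraction ids).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_config"))
  set.seed(cfg$seed)
  vis <- cfg$platform_visibility
  unit <- function(p) { v <- stats::rnorm(p); v / sqrt(sum(v^2)) }
  mean_a <- lapply(seq_len(cfg$n_classes), function(c)
    if (vis[c] %in% c("both", "A")) cfg$d * unit(cfg$features_a)
    else numeric(cfg$features_a))
  mean_b <- lapply(seq_len(cfg$n_classes), function(c)
    if (vis[c] %in% c("both", "B")) cfg$d * unit(cfg$features_b)
    else numeric(cfg$features_b))

  ref_ids <- unlist(lapply(seq_len(cfg$n_classes), function(c)
    sprintf("class%02d_m%02d", c, seq_len(cfg$members_per_class))))
  noise_ids <- sprintf("noise_%03d", seq_len(cfg$n_noise_perturbagens))
  frac_ids <- sprintf("frac_%03d", seq_len(cfg$n_fractions))
  ref_class <- rep(seq_len(cfg$n_classes), each = cfg$members_per_class)

  noise_mat <- function(n, p) matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)
  build <- function(means, p) {
    refs <- do.call(rbind, lapply(seq_along(ref_ids), function(i)
      means[[ref_class[i]]]))
    refs + noise_mat(length(ref_ids), p)
  }
  za_ref <- build(mean_a, cfg$features_a)
  zb_ref <- build(mean_b, cfg$features_b)
  za_noise <- noise_mat(cfg$n_noise_perturbagens, cfg$features_a)
  zb_noise <- noise_mat(cfg$n_noise_perturbagens, cfg$features_b)

  # bioactive compounds: one per active class, planted in disjoint fractions
  bio_classes <- seq_len(cfg$n_bioactive_classes)
  shuffled <- sample(frac_ids)
  bio_fracs <- lapply(seq_along(bio_classes), function(i)
    sort(shuffled[((i - 1L) * cfg$fractions_per_bioactive + 1L):
                  (i * cfg$fractions_per_bioactive)]))
  names(bio_fracs) <- sprintf("class%02d", bio_classes)
  frac_class <- stats::setNames(rep(NA_integer_, cfg$n_fractions), frac_ids)
  for (i in seq_along(bio_classes)) frac_class[bio_fracs[[i]]] <- bio_classes[i]

  za_frac <- noise_mat(cfg$n_fractions, cfg$features_a)
  zb_frac <- noise_mat(cfg$n_fractions, cfg$features_b)
  act <- which(!is.na(frac_class))
  for (i in act) {
    za_frac[i, ] <- za_frac[i, ] + mean_a[[frac_class[i]]]
    zb_frac[i, ] <- zb_frac[i, ] + mean_b[[frac_class[i]]]
  }

  za <- rbind(za_ref, za_noise, za_frac)
  zb <- rbind(zb_ref, zb_noise, zb_frac)
  all_ids <- c(ref_ids, noise_ids, frac_ids)
  rownames(za) <- rownames(zb) <- all_ids
  colnames(za) <- sprintf("gene%02d", seq_len(cfg$features_a))
  colnames(zb) <- sprintf("feat%03d", seq_len(cfg$features_b))
  type <- c(rep("reference", length(ref_ids) + length(noise_ids)),
            rep("fraction", length(frac_ids)))

  # compound catalogue: grid-spaced m/z so distinct compounds never collide
  # within the default matching tolerances
  n_bio <- length(bio_classes)
  comp_ids <- c(sprintf("bio_class%02d", bio_classes),
                sprintf("inert_%03d", seq_len(cfg$n_inert_compounds)))
  n_comp <- length(comp_ids)
  compounds <- data.frame(
    compound = comp_ids,
    class = c(bio_classes, rep(NA_integer_, cfg$n_inert_compounds)),
    bioactive = c(rep(TRUE, n_bio), rep(FALSE, cfg$n_inert_compounds)),
    mz = 150 + 0.7 * seq_len(n_comp) + stats::runif(n_comp, -0.2, 0.2),
    rt = stats::runif(n_comp, 0.5, 9.5),
    ccs = stats::runif(n_comp, 120, 300),
    stringsAsFactors = FALSE)

  inert_pool <- comp_ids[(n_bio + 1L):n_comp]
  frac_comp <- lapply(seq_len(cfg$n_fractions), function(i) {
    n_in <- sample(3:10, 1L)
    picked <- sample(inert_pool, min(n_in, length(inert_pool)))
    if (!is.na(frac_class[i]))
      picked <- c(sprintf("bio_class%02d", frac_class[i]), picked)
    sort(picked)
  })
  names(frac_comp) <- frac_ids

  ann <- annotation_table(
    c(ref_ids, noise_ids, frac_ids),
    c(sprintf("class%02d", ref_class),
      rep("none", length(noise_ids) + length(frac_ids))))

  pa <- profile_matrix(za, type = type, platform = "FUSION")
  pb <- profile_matrix(zb, type = type, platform = "CP")
  list(profile_a = pa, profile_b = pb, annotations = ann,
       truth = list(
         perturbagen_class = stats::setNames(sprintf("class%02d", ref_class),
                                             ref_ids),
         class_visibility = stats::setNames(vis,
                                            sprintf("class%02d",
                                                    seq_len(cfg$n_classes))),
         fraction_compounds = frac_comp,
         compounds = compounds,
         bioactive_fractions = bio_fracs,
         fraction_class = frac_class),
       config = cfg)
}

#' Simulate replicate-level metabolomics feature observations
#'
#' Every compound present in a fraction emits one feature per technical
#' replicate (3 by default) with Gaussian m/z and RT jitter; `dropout` makes
#' individual replicate observations vanish, so some features appear in only
#' 1 of 3 replicates and must be removed by the consensus rule. Each fraction
#' additionally emits `n_decoys` sample-unique decoy features (seen in all
#' replicates) that basket as singletons.
#'
#' @param truth The `truth` element of [simulate_screen()] output.
#' @param seed RNG seed.
#' @param n_replicates Technical replicates (default 3).
#' @param mz_jitter_sd m/z jitter sd in Th (default 0.002).
#' @param rt_jitter_sd RT jitter sd in minutes (default 0.03).
#' @param dropout Per-replicate observation dropout probability (default
#'   0.1).
#' @param n_decoys Decoy features per fraction (default 3).
#' @return Data frame of feature observations (columns `sample`,
#'   `replicate`, `mz`, `rt`, `ccs`, `intensity`).
#' @export
simulate_metabolome <- function(truth, seed, n_replicates = 3L,
                                mz_jitter_sd = 0.002, rt_jitter_sd = 0.03,
                                dropout = 0.1, n_decoys = 3L) {
  set.seed(seed)
  comp <- truth$compounds
  fracs <- names(truth$fraction_compounds)
  decoy_mz0 <- 150 + 0.7 * (nrow(comp) + 1L)
  decoy_counter <- 0L
  rows <- vector("list", length(fracs))
  for (fi in seq_along(fracs)) {
    f <- fracs[fi]
    present <- truth$fraction_compounds[[f]]
    idx <- match(present, comp$compound)
    base_int <- stats::rlnorm(length(idx), meanlog = 10, sdlog = 1)
    part <- list()
    for (r in seq_len(n_replicates)) {
      emit <- stats::runif(length(idx)) >= dropout
      if (!any(emit)) next
      k <- idx[emit]
      part[[length(part) + 1L]] <- data.frame(
        sample = f, replicate = r,
        mz = comp$mz[k] + stats::rnorm(sum(emit), sd = mz_jitter_sd),
        rt = pmax(0, comp$rt[k] + stats::rnorm(sum(emit), sd = rt_jitter_sd)),
        ccs = comp$ccs[k] * (1 + stats::rnorm(sum(emit), sd = 0.005)),
        intensity = base_int[emit] * stats::rlnorm(sum(emit), sdlog = 0.2),
        stringsAsFactors = FALSE)
    }
    if (n_decoys > 0L) {
      dmz <- decoy_mz0 + 0.7 * (decoy_counter + seq_len(n_decoys)) +
        stats::runif(n_decoys, -0.2, 0.2)
      drt <- stats::runif(n_decoys, 0.5, 9.5)
      dccs <- stats::runif(n_decoys, 120, 300)
      dint <- stats::rlnorm(n_decoys, meanlog = 9, sdlog = 1)
      decoy_counter <- decoy_counter + n_decoys
      for (r in seq_len(n_replicates)) {
        part[[length(part) + 1L]] <- data.frame(
          sample = f, replicate = r,
          mz = dmz + stats::rnorm(n_decoys, sd = mz_jitter_sd),
          rt = pmax(0, drt + stats::rnorm(n_decoys, sd = rt_jitter_sd)),
          ccs = dccs, intensity = dint, stringsAsFactors = FALSE)
      }
    }
    rows[[fi]] <- do.call(rbind, part)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all simulated inputs as the delimited files the readers consume
#'
#' @param sim Output of [simulate_screen()].
#' @param obs Optional output of [simulate_metabolome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_screen <- function(sim, dir, obs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_table(sim$profile_a, file.path(dir, "fusion_z.csv"))
  write_profile_table(sim$profile_b, file.path(dir, "cp_z.csv"))
  utils::write.table(sim$annotations, file.path(dir, "annotations.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  meta <- data.frame(id = sim$profile_a$perturbagen_meta$id,
                     type = sim$profile_a$perturbagen_meta$type)
  utils::write.table(meta, file.path(dir, "perturbagen_meta.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(obs)) {
    num <- vapply(obs, is.numeric, logical(1L))
    o <- obs
    o[num] <- lapply(o[num], function(col) formatC(col, digits = 17, format = "g"))
    utils::write.table(o, file.path(dir, "features.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
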