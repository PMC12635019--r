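# Synthetic DNAm cohort generator.
#
# Emulates the statistical structure of blood methylation cohorts used to
# train and audit linear age clocks: age-linear CpGs (slope 0.008/year),
# exactly or noisily collinear CpGs, age-independent normal/uniform CpGs,
# cell-type-mixture CpGs driven by a 12-leukocyte composition with an
# age-declining naive T compartment and a disease-driven myeloid shift, and
# heteroscedastic noise whose SD follows a piecewise-linear age trajectory.

DEFAULT_CELL_TYPES <- c(
  "CD4T_naive", "CD4T_memory", "CD8T_naive", "CD8T_memory",
  "B_naive", "B_memory", "Treg", "NK",
  "Monocytes", "Neutrophils", "Eosinophils", "Basophils"
)

#' Piecewise noise trajectory specification
#'
#' Describes how the per-CpG noise SD (beta units) changes with age: linear
#' in age within each segment, continuous at the breakpoints. The default
#' encodes rising noise from young adulthood to the mid-30s, a plateau to
#' the late 40s, a second rise to 60 and stability after.
#'
#' @param breakpoints Strictly increasing ages (years); default `c(36, 48, 60)`.
#' @param slopes SD slope per segment (beta units/year), one more than the
#'   number of breakpoints; default `c(0.0015, 0, 0.001, 0)`.
#' @param base_sd SD at `anchor_age` (beta units, > 0); default 0.03.
#' @param anchor_age Age at which `base_sd` applies; default 20.
#' @param disease_sd_multiplier Multiplier (>= 1) applied to the SD of
#'   disease-labeled samples; default 1.5.
#' @return An object of class `piecewise_noise_spec`.
#' @export
piecewise_noise_spec <- function(breakpoints = c(36, 48, 60),
                                 slopes = c(0.0015, 0, 0.001, 0),
                                 base_sd = 0.03,
                                 anchor_age = 20,
                                 disease_sd_multiplier = 1.5) {
  if (length(breakpoints) && any(diff(breakpoints) <= 0)) {
    stop_input("breakpoints must be strictly increasing")
  }
  if (length(slopes) != length(breakpoints) + 1L) {
    stop_input("need one SD slope per segment (breakpoints + 1)")
  }
  if (!is_scalar_num(base_sd) || base_sd <= 0) stop_input("base_sd must be > 0")
  if (disease_sd_multiplier < 1) stop_input("disease_sd_multiplier must be >= 1")
  structure(list(breakpoints = as.numeric(breakpoints),
                 slopes = as.numeric(slopes),
                 base_sd = base_sd, anchor_age = anchor_age,
                 disease_sd_multiplier = disease_sd_multiplier),
            class = "piecewise_noise_spec")
}

#' Evaluate a piecewise noise trajectory
#'
#' @param ages Numeric vector of ages (years).
#' @param spec A [piecewise_noise_spec()].
#' @return SD (beta units) at each age, floored at 1e-4.
#' @export
piecewise_sd <- function(ages, spec) {
  stopifnot(inherits(spec, "piecewise_noise_spec"))
  lo <- c(spec$anchor_age, spec$breakpoints)
  hi <- c(spec$breakpoints, Inf)
  sd <- rep(spec$base_sd, length(ages))
  for (s in seq_along(spec$slopes)) {
    run <- pmax(0, pmin(ages, hi[s]) - lo[s])
    sd <- sd + spec$slopes[s] * run
  }
  # below the anchor, extrapolate the first segment
  below <- ages < spec$anchor_age
  if (any(below)) {
    sd[below] <- spec$base_sd + spec$slopes[1L] * (ages[below] - spec$anchor_age)
  }
  pmax(sd, 1e-4)
}

#' Leukocyte mixture specification
#'
#' Twelve immune cell types with per-type mean fractions, per-year age
#' slopes (naive T compartments decline with age; neutrophils are stable),
#' a disease-driven lymphoid-to-myeloid shift, and a Dirichlet concentration
#' controlling inter-individual dispersion around the age/status-adjusted
#' mean composition.
#'
#' @param cell_types Character vector of exactly 12 labels.
#' @param base_fractions Mean fractions at the reference age (45 y); must be
#'   positive and is normalized to sum to 1.
#' @param age_slopes Fraction change per year for each cell type.
#' @param disease_shift Additive fraction shift applied to disease samples
#'   (myeloid up, naive lymphoid down by default).
#' @param dirichlet_concentration Total Dirichlet concentration (> 0);
#'   larger means tighter compositions. Default 200.
#' @param reference_profiles Optional cell_type x CpG matrix of mean beta
#'   values in \[0,1\] used for mixture CpGs; when `NULL`, profiles are drawn
#'   per cohort from its seed (see [make_reference_profiles()]).
#' @return An object of class `cell_mix_spec`.
#' @export
cell_mix_spec <- function(cell_types = DEFAULT_CELL_TYPES,
                          base_fractions = c(0.08, 0.08, 0.05, 0.05, 0.03,
                                             0.02, 0.02, 0.07, 0.08, 0.45,
                                             0.05, 0.02),
                          age_slopes = c(-0.0012, 0.0008, -0.0010, 0.0008,
                                         -0.0004, 0.0002, 0, 0, 0, 0, 0, 0),
                          disease_shift = c(-0.03, 0, -0.02, 0, -0.01, 0, 0,
                                            0, 0.02, 0.04, 0, 0),
                          dirichlet_concentration = 200,
                          reference_profiles = NULL) {
  if (length(cell_types) != 12L || anyDuplicated(cell_types)) {
    stop_input("cell_mix_spec requires exactly 12 unique cell types")
  }
  if (length(base_fractions) != 12L || any(base_fractions <= 0)) {
    stop_input("base_fractions must be 12 positive values")
  }
  if (length(age_slopes) != 12L || length(disease_shift) != 12L) {
    stop_input("age_slopes and disease_shift must have length 12")
  }
  if (dirichlet_concentration <= 0) stop_input("dirichlet_concentration must be > 0")
  if (!is.null(reference_profiles)) {
    reference_profiles <- as.matrix(reference_profiles)
    if (nrow(reference_profiles) != 12L ||
        any(reference_profiles < 0 | reference_profiles > 1)) {
      stop_input("reference_profiles must be a 12 x CpG matrix of values in [0,1]")
    }
    rownames(reference_profiles) <- cell_types
  }
  structure(list(cell_types = cell_types,
                 base_fractions = base_fractions / sum(base_fractions),
                 age_slopes = as.numeric(age_slopes),
                 disease_shift = as.numeric(disease_shift),
                 dirichlet_concentration = dirichlet_concentration,
                 reference_profiles = reference_profiles),
            class = "cell_mix_spec")
}

#' Draw cell-type reference beta profiles
#'
#' Per-CpG mean beta for each of the 12 cell types, drawn uniformly on
#' \[0.1, 0.9\] so that profiles are linearly independent with high
#' probability and mixtures are identifiable.
#'
#' @param n_cpgs Number of mixture CpGs.
#' @param seed Integer seed.
#' @param cell_types Row labels.
#' @return A 12 x `n_cpgs` matrix.
#' @export
make_reference_profiles <- function(n_cpgs, seed,
                                    cell_types = DEFAULT_CELL_TYPES) {
  with_seed(seed, {
    m <- matrix(stats::runif(12L * n_cpgs, 0.1, 0.9), nrow = 12L,
                dimnames = list(cell_types,
                                sprintf("cg_mix%04d", seq_len(n_cpgs))))
    m
  })
}

#' Cohort generation specification
#'
#' Houses every generative parameter of a synthetic cohort. CpG archetypes:
#' \describe{
#'   \item{age_linear}{`beta = 0.008 * age + noise`, plus an optional
#'     disease offset expressed in prediction-equivalent years.}
#'   \item{collinear}{0.5 x the first age-linear CpG (exactly, or plus noise
#'     in `"noisy"` mode).}
#'   \item{normal}{Gaussian draws independent of age, plus noise.}
#'   \item{uniform}{Uniform draws independent of age, plus noise.}
#'   \item{mixture}{Bulk signal `sum_k f_k * reference_k` from the realized
#'     leukocyte fractions, plus trajectory noise.}
#'   \item{homeostatic}{Constant mean 0.5 with trajectory noise: the
#'     stable-mean / rising-SD loci the noise barometer targets.}
#'   \item{disease}{Weak age slope plus a strong additive disease shift:
#'     high-variance disease-informative loci whose effect a residual-
#'     minimizing fitter tends to cancel.}
#' }
#'
#' @param n_samples Number of samples (>= 2).
#' @param age_range Length-2 numeric, low < high; default `c(20, 80)`.
#' @param age_distribution `"uniform"` or `"empirical-weights"`.
#' @param age_weights For `"empirical-weights"`: a data.frame with columns
#'   `age` and `weight`.
#' @param disease_fraction Proportion of disease-labeled samples in \[0,1\].
#' @param n_cpgs_by_archetype Named counts over the archetypes above.
#' @param noise A [piecewise_noise_spec()].
#' @param cell_mix A [cell_mix_spec()].
#' @param age_slope Beta-units per year for age-linear CpGs; default 0.008.
#' @param archetype_noise_sd Constant noise SD for the normal/uniform
#'   archetypes and the Fig-1D-style 5-CpG block; default 0.04.
#' @param collinear_mode `"exact"` (default) or `"noisy"`.
#' @param collinear_noise_sd SD added in `"noisy"` mode; default 0.01.
#' @param disease_shift_years Disease offset on age-linear CpGs, expressed
#'   in years (converted to beta units via `age_slope`); default 0.
#' @param disease_cpg_age_slope,disease_cpg_delta,disease_cpg_sd Generative
#'   parameters of the `disease` archetype.
#' @param seed Integer seed; identical specs reproduce identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples,
                        age_range = c(20, 80),
                        age_distribution = c("uniform", "empirical-weights"),
                        age_weights = NULL,
                        disease_fraction = 0,
                        n_cpgs_by_archetype = c(age_linear = 2, collinear = 1,
                                                normal = 1, uniform = 1,
                                                mixture = 40, homeostatic = 10,
                                                disease = 0),
                        noise = piecewise_noise_spec(),
                        cell_mix = cell_mix_spec(),
                        age_slope = 0.008,
                        archetype_noise_sd = 0.04,
                        collinear_mode = c("exact", "noisy"),
                        collinear_noise_sd = 0.01,
                        disease_shift_years = 0,
                        disease_cpg_age_slope = 0.0015,
                        disease_cpg_delta = 0.10,
                        disease_cpg_sd = 0.03,
                        seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  collinear_mode <- match.arg(collinear_mode)
  if (!is_count(n_samples) || n_samples < 2) stop_input("n_samples must be >= 2")
  if (length(age_range) != 2L || age_range[1L] >= age_range[2L]) {
    stop_input("age_range must be (low, high) with low < high")
  }
  if (disease_fraction < 0 || disease_fraction > 1) {
    stop_input("disease_fraction must lie in [0,1]")
  }
  known <- c("age_linear", "collinear", "normal", "uniform", "mixture",
             "homeostatic", "disease")
  counts <- stats::setNames(rep(0L, length(known)), known)
  bad <- setdiff(names(n_cpgs_by_archetype), known)
  if (length(bad)) stop_input("unknown archetype(s): %s", paste(bad, collapse = ", "))
  counts[names(n_cpgs_by_archetype)] <- as.integer(n_cpgs_by_archetype)
  if (any(counts < 0)) stop_input("archetype counts must be >= 0")
  if (counts["collinear"] > 0 && counts["age_linear"] == 0) {
    stop_input("collinear CpGs require at least one age_linear CpG")
  }
  if (age_distribution == "empirical-weights") {
    if (is.null(age_weights) || !all(c("age", "weight") %in% names(age_weights))) {
      stop_input("empirical-weights needs age_weights with columns age, weight")
    }
  }
  stopifnot(inherits(noise, "piecewise_noise_spec"),
            inherits(cell_mix, "cell_mix_spec"))
  structure(list(n_samples = as.integer(n_samples), age_range = age_range,
                 age_distribution = age_distribution, age_weights = age_weights,
                 disease_fraction = disease_fraction,
                 n_cpgs_by_archetype = counts, noise = noise,
                 cell_mix = cell_mix, age_slope = age_slope,
                 archetype_noise_sd = archetype_noise_sd,
                 collinear_mode = collinear_mode,
                 collinear_noise_sd = collinear_noise_sd,
                 disease_shift_years = disease_shift_years,
                 disease_cpg_age_slope = disease_cpg_age_slope,
                 disease_cpg_delta = disease_cpg_delta,
                 disease_cpg_sd = disease_cpg_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Inflammaging cohort preset
#'
#' A cohort in which disease samples look "biologically older": age-linear
#' CpGs carry a +5-year disease offset, disease-archetype CpGs carry a
#' strong additive shift with only a weak age slope, the leukocyte mix
#' undergoes the myeloid shift, and disease noise is inflated. This is the
#' stated world for the accuracy-vs-separation trade-off experiment.
#'
#' @param n_samples Cohort size; default 1000.
#' @param seed Integer seed.
#' @param disease_fraction Default 0.5 (balanced case/control).
#' @param ... Overrides forwarded to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
inflammaging_cohort_spec <- function(n_samples = 1000, seed = 1L,
                                     disease_fraction = 0.5, ...) {
  cohort_spec(n_samples = n_samples, seed = seed,
              disease_fraction = disease_fraction,
              n_cpgs_by_archetype = c(age_linear = 4, collinear = 1,
                                      normal = 2, uniform = 2, mixture = 24,
                                      homeostatic = 6, disease = 6),
              disease_shift_years = 5, ...)
}

#' Generate the five-CpG archetype block
#'
#' The didactic construction: CpGs 1 and 2 both equal `0.008 * age` plus
#' Gaussian noise, CpG 3 is half of CpG 1 (exactly, or plus noise), CpG 4 is
#' normally distributed and CpG 5 uniformly distributed, both age-independent
#' with added Gaussian noise. All values are clipped to \[0,1\].
#'
#' @param ages Non-empty numeric vector of ages in \[0, 120\].
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise SD (beta units); default 0.04. Zero gives
#'   the noiseless limit (column 1 equals `0.008 * age` exactly).
#' @param collinear_mode `"exact"` or `"noisy"` for CpG 3.
#' @param collinear_noise_sd SD for `"noisy"` CpG 3; default 0.01.
#' @return A list with `beta` (length(ages) x 5 matrix, columns
#'   `cg_arch1`..`cg_arch5`) and `labels` (per-column archetype).
#' @examples
#' generate_archetype_cpgs(c(25, 50, 75), seed = 1, noise_sd = 0)$beta
#' @export
generate_archetype_cpgs <- function(ages, seed, noise_sd = 0.04,
                                    collinear_mode = c("exact", "noisy"),
                                    collinear_noise_sd = 0.01) {
  collinear_mode <- match.arg(collinear_mode)
  if (length(ages) == 0L) stop_input("ages must be non-empty")
  if (any(!is.finite(ages)) || any(ages < 0 | ages > 120)) {
    stop_input("ages must lie in [0, 120]")
  }
  n <- length(ages)
  with_seed(seed, {
    noise <- function() stats::rnorm(n, 0, noise_sd)
    c1 <- clip01(0.008 * ages + noise())
    c2 <- clip01(0.008 * ages + noise())
    c3 <- 0.5 * c1
    if (collinear_mode == "noisy") {
      c3 <- clip01(c3 + stats::rnorm(n, 0, collinear_noise_sd))
    }
    c4 <- clip01(stats::rnorm(n, 0.5, 0.1) + noise())
    c5 <- clip01(stats::runif(n, 0, 1) + noise())
    beta <- cbind(cg_arch1 = c1, cg_arch2 = c2, cg_arch3 = c3,
                  cg_arch4 = c4, cg_arch5 = c5)
    labels <- c(cg_arch1 = "age_linear", cg_arch2 = "age_linear",
                cg_arch3 = "collinear", cg_arch4 = "normal",
                cg_arch5 = "uniform")
    list(beta = beta, labels = labels)
  })
}

# Draw Dirichlet fractions around per-sample mean compositions.
draw_fractions <- function(ages, disease, mix) {
  n <- length(ages)
  out <- matrix(0, n, 12L, dimnames = list(NULL, mix$cell_types))
  floored <- 0L
  for (i in seq_len(n)) {
    m <- mix$base_fractions + mix$age_slopes * (ages[i] - 45) +
      if (disease[i]) mix$disease_shift else 0
    if (any(m < 0)) { floored <- floored + 1L; m <- pmax(m, 0) }
    if (sum(m) == 0) stop_input("degenerate mixture means (all zero)")
    m <- m / sum(m)
    g <- stats::rgamma(12L, shape = m * mix$dirichlet_concentration, rate = 1)
    # guard against all-zero gamma draws at tiny shapes
    if (sum(g) == 0) g <- m
    out[i, ] <- g / sum(g)
  }
  if (floored > 0L) {
    warning(sprintf("negative mixture means floored and renormalized for %d sample(s)",
                    floored))
  }
  out
}

#' Generate a synthetic cohort
#'
#' Assembles ages, health status, leukocyte fractions and all requested CpG
#' archetype blocks into a beta matrix, with ground truth retained for
#' parameter-recovery tests. Identical specs (including seed) reproduce
#' identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with `beta`
#'   ([beta_matrix()]), `metadata` (sample_id/age/status), `true_fractions`
#'   (samples x 12), `archetype_labels`, `truth` (per-CpG generative
#'   parameters), `reference_profiles`, and the originating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  counts <- spec$n_cpgs_by_archetype
  n <- spec$n_samples
  with_seed(spec$seed, {
    ages <- if (spec$age_distribution == "uniform") {
      stats::runif(n, spec$age_range[1L], spec$age_range[2L])
    } else {
      sample(spec$age_weights$age, n, replace = TRUE,
             prob = spec$age_weights$weight)
    }
    n_dis <- round(n * spec$disease_fraction)
    disease <- rep(FALSE, n)
    if (n_dis > 0) disease[sample.int(n, n_dis)] <- TRUE
    sd_mult <- ifelse(disease, spec$noise$disease_sd_multiplier, 1)
    traj_sd <- piecewise_sd(ages, spec$noise) * sd_mult

    fractions <- draw_fractions(ages, disease, spec$cell_mix)
    ref <- spec$cell_mix$reference_profiles
    if (counts["mixture"] > 0 && is.null(ref)) {
      ref <- make_reference_profiles(counts["mixture"],
                                     derive_seed(spec$seed, "reference"),
                                     spec$cell_mix$cell_types)
    }

    blocks <- list(); labels <- character(0); truth <- list()
    add_block <- function(betas, ids, archetype, slope = 0, delta = 0) {
      betas <- matrix(betas, nrow = n, dimnames = list(NULL, ids))
      blocks[[length(blocks) + 1L]] <<- betas
      labels <<- c(labels, stats::setNames(rep(archetype, length(ids)), ids))
      truth[[length(truth) + 1L]] <<- data.frame(
        cpg_id = ids, archetype = archetype, age_slope = slope,
        disease_delta = delta, stringsAsFactors = FALSE)
    }

    dis_delta_beta <- spec$disease_shift_years * spec$age_slope
    if (counts["age_linear"] > 0) {
      k <- counts["age_linear"]
      b <- sapply(seq_len(k), function(j) {
        clip01(spec$age_slope * ages + dis_delta_beta * disease +
                 stats::rnorm(n, 0, traj_sd))
      })
      add_block(b, sprintf("cg_age%04d", seq_len(k)), "age_linear",
                spec$age_slope, dis_delta_beta)
    }
    if (counts["collinear"] > 0) {
      k <- counts["collinear"]
      parent <- blocks[[1L]][, 1L]
      b <- sapply(seq_len(k), function(j) {
        x <- 0.5 * parent
        if (spec$collinear_mode == "noisy") {
          x <- clip01(x + stats::rnorm(n, 0, spec$collinear_noise_sd))
        }
        x
      })
      add_block(b, sprintf("cg_col%04d", seq_len(k)), "collinear",
                0.5 * spec$age_slope, 0.5 * dis_delta_beta)
    }
    if (counts["normal"] > 0) {
      k <- counts["normal"]
      b <- sapply(seq_len(k), function(j) {
        clip01(stats::rnorm(n, 0.5, 0.1) +
                 stats::rnorm(n, 0, spec$archetype_noise_sd))
      })
      add_block(b, sprintf("cg_nrm%04d", seq_len(k)), "normal")
    }
    if (counts["uniform"] > 0) {
      k <- counts["uniform"]
      b <- sapply(seq_len(k), function(j) {
        clip01(stats::runif(n) + stats::rnorm(n, 0, spec$archetype_noise_sd))
      })
      add_block(b, sprintf("cg_unf%04d", seq_len(k)), "uniform")
    }
    if (counts["mixture"] > 0) {
      k <- counts["mixture"]
      bulk <- fractions %*% ref[, seq_len(k), drop = FALSE]
      b <- clip01(bulk + matrix(stats::rnorm(n * k, 0, traj_sd), n, k))
      add_block(b, colnames(ref)[seq_len(k)], "mixture")
    }
    if (counts["homeostatic"] > 0) {
      k <- counts["homeostatic"]
      b <- sapply(seq_len(k), function(j) clip01(0.5 + stats::rnorm(n, 0, traj_sd)))
      add_block(b, sprintf("cg_hom%04d", seq_len(k)), "homeostatic")
    }
    if (counts["disease"] > 0) {
      k <- counts["disease"]
      b <- sapply(seq_len(k), function(j) {
        clip01(0.25 + spec$disease_cpg_age_slope * ages +
                 spec$disease_cpg_delta * disease +
                 stats::rnorm(n, 0, spec$disease_cpg_sd * sd_mult))
      })
      add_block(b, sprintf("cg_dis%04d", seq_len(k)), "disease",
                spec$disease_cpg_age_slope, spec$disease_cpg_delta)
    }
    if (!length(blocks)) stop_input("cohort spec requests zero CpGs")

    beta <- beta_matrix(do.call(cbind, blocks),
                        sample_ids = sprintf("S%05d", seq_len(n)))
    metadata <- data.frame(
      sample_id = rownames(beta), age = ages,
      status = ifelse(disease, "disease", "healthy"),
      stringsAsFactors = FALSE)
    rownames(fractions) <- rownames(beta)
    structure(list(beta = beta, metadata = metadata,
                   true_fractions = fractions,
                   archetype_labels = labels,
                   truth = do.call(rbind, truth),
                   reference_profiles = ref, spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples x %d CpGs (%d disease)\n",
              nrow(x$beta), ncol(x$beta), sum(x$metadata$status == "disease")))
  invisible(x)
}

#' Write a cohort to delimited files
#'
#' Emits `beta.tsv` (CpGs in rows), `metadata.tsv`, `true_fractions.tsv`,
#' `truth.tsv` and, when present, `reference_profiles.tsv`. All files
#' round-trip losslessly (<= 1e-9 relative) through the package readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (ncol(cohort$beta) == 0L || nrow(cohort$beta) == 0L) {
    stop_input("refusing to write an empty cohort")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(directory, "beta.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             fractions = file.path(directory, "true_fractions.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_beta_matrix(cohort$beta, paths["beta"])
  write_sample_metadata(cohort$metadata, paths["metadata"])
  fr <- cbind(sample_id = rownames(cohort$true_fractions),
              as.data.frame(apply(cohort$true_fractions, 2L, fmt_num),
                            stringsAsFactors = FALSE))
  utils::write.table(fr, paths["fractions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- cohort$truth
  tr$age_slope <- fmt_num(tr$age_slope)
  tr$disease_delta <- fmt_num(tr$disease_delta)
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cohort$reference_profiles)) {
    paths <- c(paths, reference = file.path(directory, "reference_profiles.tsv"))
    rp <- cbind(cell_type = rownames(cohort$reference_profiles),
                as.data.frame(apply(cohort$reference_profiles, 2L, fmt_num),
                              stringsAsFactors = FALSE, check.names = FALSE))
    utils::write.table(rp, paths["reference"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a written cohort back
#'
#' @param directory Directory previously written by [write_cohort()].
#' @return A list with `beta`, `metadata`, `true_fractions`, `truth` and
#'   (if present) `reference_profiles`.
#' @export
read_cohort <- function(directory) {
  beta <- read_beta_matrix(file.path(directory, "beta.tsv"),
                           orientation = "cpgs-in-rows")
  metadata <- read_sample_metadata(file.path(directory, "metadata.tsv"))
  fr <- utils::read.table(file.path(directory, "true_fractions.tsv"),
                          sep = "\t", header = TRUE, check.names = FALSE)
  fractions <- as.matrix(fr[, -1L, drop = FALSE])
  rownames(fractions) <- fr[[1L]]
  truth <- utils::read.table(file.path(directory, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  out <- list(beta = beta, metadata = metadata, true_fractions = fractions,
              truth = truth)
  ref_path <- file.path(directory, "reference_profiles.tsv")
  if (file.exists(ref_path)) {
    rp <- utils::read.table(ref_path, sep = "\t", header = TRUE,
                            check.names = FALSE)
    ref <- as.matrix(rp[, -1L, drop = FALSE])
    rownames(ref) <- rp[[1L]]
    out$reference_profiles <- ref
  }
  out
}
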