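#' Specification of a synthetic multi-cohort expression study
#'
#' Describes the generative process used by [generate_cohorts()]: `m` genes
#' with heterogeneous noise (per-gene SD drawn uniformly from
#' `sigma_range`), `k` gene-disjoint planted pairs whose class-conditional
#' means are reversed between classes with effect size `delta` (in pooled
#' noise-SD units), and an optional cohort-level batch transform. Batch
#' modes: `"none"`, `"affine"` (a global `s * X + c` per cohort, which the
#' ternary pair coding cancels exactly), and `"nonaffine"` (a strong global
#' affine rescaling -- emulating a dynamic-range difference between
#' platforms (defaults 3 and 10) -- plus per-gene offsets of SD `gene_shift_sd` times each
#' gene's noise SD, emulating probe-level effects; this deliberately breaks
#' exact affine invariance).
#'
#' @param m Number of genes.
#' @param n Samples per cohort.
#' @param z Number of classes.
#' @param class_props Class proportions (length `z`, summing to 1); equal by
#'   default.
#' @param k Number of planted pairs (`k <= floor(m / 2)`; pairs are
#'   gene-disjoint so ground truth is unambiguous).
#' @param delta Effect size: each planted gene's class-conditional mean sits
#'   at `mu +/- delta * sigma_bar` where `sigma_bar` is the pair's pooled
#'   noise SD; the two genes move in opposite directions and swap between
#'   classes.
#' @param sigma_range Range of per-gene noise SDs (`sigma_lo > 0`).
#' @param mu_range Range of per-gene baseline means (expression units).
#' @param batch Batch model applied to every cohort after the first.
#' @param batch_scale,batch_shift Global affine parameters of the
#'   `"nonaffine"` mode (defaults 3 and 10).
#' @param gene_shift_sd Per-gene offset SD multiplier of the `"nonaffine"`
#'   mode (default 0.75).
#' @param noise `"normal"` (default) or `"lognormal"` (values exponentiated
#'   for TPM-like skew).
#' @param dropout Probability of zeroing an entry (crude dropout toggle).
#' @param survival_hr Optional hazard ratio; when set, exponential survival
#'   outcomes are attached (see [survival_from_labels()]).
#' @param censor_rate Expected fraction of censored samples.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 300L, n = 150L, z = 2L, class_props = NULL,
                           k = 15L, delta = 3,
                           sigma_range = c(0.5, 1.5), mu_range = c(4, 10),
                           batch = c("none", "affine", "nonaffine"),
                           batch_scale = 3, batch_shift = 10,
                           gene_shift_sd = 0.75,
                           noise = c("normal", "lognormal"),
                           dropout = 0, survival_hr = NULL,
                           censor_rate = 0.2) {
  batch <- match.arg(batch)
  noise <- match.arg(noise)
  if (is.null(class_props)) class_props <- rep(1 / z, z)
  stopifnot(m >= 2, n >= 4, z >= 2, length(class_props) == z,
            abs(sum(class_props) - 1) < 1e-8,
            delta >= 0, sigma_range[1L] > 0, sigma_range[2L] >= sigma_range[1L],
            dropout >= 0, dropout < 1)
  if (k > floor(m / 2)) {
    stop("k planted pairs need 2k distinct genes (k <= floor(m/2))",
         call. = FALSE)
  }
  if (!is.null(survival_hr) && survival_hr <= 0) {
    stop("survival hazard ratio must be > 0", call. = FALSE)
  }
  structure(list(m = as.integer(m), n = as.integer(n), z = as.integer(z),
                 class_props = class_props, k = as.integer(k), delta = delta,
                 sigma_range = sigma_range, mu_range = mu_range,
                 batch = batch, batch_scale = batch_scale,
                 batch_shift = batch_shift, gene_shift_sd = gene_shift_sd,
                 noise = noise, dropout = dropout,
                 survival_hr = survival_hr, censor_rate = censor_rate),
            class = "synthetic_spec")
}

cohort_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) + 7919 * idx) %% 2147483647)
}

#' Generate synthetic cohorts with planted pair reversals
#'
#' Gene-level parameters (baseline means, noise SDs, planted-pair gene
#' assignment) are drawn once from `seed`, then each cohort's expression,
#' labels and batch transform are drawn from a seed derived
#' deterministically from `(seed, cohort index)`, so any cohort is
#' reproducible in isolation. The first cohort is the untransformed
#' reference; later cohorts receive the spec's batch transform. Planted
#' pairs reverse between the first class and the rest (with more than two
#' classes, the reversed class cycles over classes so every class carries
#' signal). Ground truth (the planted pair list) is returned in
#' machine-readable form.
#'
#' @param spec A [synthetic_spec()].
#' @param n_cohorts Number of cohorts to generate.
#' @param seed Integer master seed.
#' @return List of `synthetic_cohort` objects: each has `X` (expression
#'   matrix), `labels` (named factor), `truth` (data.frame `gene_a`,
#'   `gene_b`, `up_class`), `survival` (or `NULL`), `batch` (parameters
#'   applied), `seed`.
#' @export
generate_cohorts <- function(spec, n_cohorts = 1L, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  mu <- stats::runif(spec$m, spec$mu_range[1L], spec$mu_range[2L])
  sds <- stats::runif(spec$m, spec$sigma_range[1L], spec$sigma_range[2L])
  genes <- sprintf("G%04d", seq_len(spec$m))
  plant_genes <- sample(spec$m, 2L * spec$k)
  pa <- plant_genes[seq_len(spec$k) * 2L - 1L]
  pb <- plant_genes[seq_len(spec$k) * 2L]
  up_class <- if (spec$z == 2L) rep(1L, spec$k)
              else ((seq_len(spec$k) - 1L) %% spec$z) + 1L
  truth <- data.frame(gene_a = genes[pa], gene_b = genes[pb],
                      up_class = paste0("class", up_class, recycle0 = TRUE),
                      stringsAsFactors = FALSE)
  class_n <- floor(spec$class_props * spec$n)
  class_n[1L] <- spec$n - sum(class_n[-1L])
  cls <- rep(seq_len(spec$z), class_n)
  lapply(seq_len(n_cohorts), function(ci) {
    cs <- cohort_seed(seed, ci)
    set.seed(cs)
    cname <- paste0("cohort", ci)
    sample_ids <- sprintf("%s_s%03d", cname, seq_len(spec$n))
    X <- matrix(stats::rnorm(spec$m * spec$n, mean = mu, sd = sds),
                nrow = spec$m, ncol = spec$n)
    for (p in seq_len(spec$k)) {
      a <- pa[p]; b <- pb[p]
      pool <- sqrt((sds[a]^2 + sds[b]^2) / 2)
      up <- cls == up_class[p]
      shift <- ifelse(up, 1, -1) * spec$delta * pool
      X[a, ] <- stats::rnorm(spec$n, mu[a] + shift, sds[a])
      X[b, ] <- stats::rnorm(spec$n, mu[b] - shift, sds[b])
    }
    batch <- list(mode = "none")
    if (ci > 1L && spec$batch == "affine") {
      s <- stats::runif(1L, 0.8, 1.6)
      c0 <- stats::runif(1L, -2, 4)
      X <- s * X + c0
      batch <- list(mode = "affine", scale = s, shift = c0)
    } else if (ci > 1L && spec$batch == "nonaffine") {
      gshift <- stats::rnorm(spec$m, 0, spec$gene_shift_sd * sds)
      X <- spec$batch_scale * X + spec$batch_shift + gshift
      batch <- list(mode = "nonaffine", scale = spec$batch_scale,
                    shift = spec$batch_shift, gene_shift = gshift)
    }
    if (spec$noise == "lognormal") X <- exp(X / 2)
    if (spec$dropout > 0) {
      drop <- matrix(stats::runif(spec$m * spec$n) < spec$dropout,
                     spec$m, spec$n)
      X[drop] <- 0
    }
    dimnames(X) <- list(genes, sample_ids)
    X <- expression_matrix(X, cname)
    labels <- label_map(stats::setNames(paste0("class", cls), sample_ids),
                        class_order = paste0("class", seq_len(spec$z)))
    surv <- if (!is.null(spec$survival_hr)) {
      survival_from_labels(labels, hr = spec$survival_hr,
                           censor_rate = spec$censor_rate, seed = cs + 1L)
    }
    structure(list(X = X, labels = labels, truth = truth, survival = surv,
                   batch = batch, seed = cs),
              class = "synthetic_cohort")
  })
}

#' Exponential survival outcomes conditional on class
#'
#' Event times are exponential with a class-dependent hazard: the first
#' class (responders) has the baseline hazard and every other class has
#' `hr` times the baseline. Censoring is independent per sample, drawn as a
#' competing exponential whose rate is calibrated so the expected censored
#' fraction equals `censor_rate`; observed time is the minimum of the two.
#' A censoring rate of 1 (or data that happen to contain no events) is an
#' error.
#'
#' @param labels Named factor of class labels.
#' @param hr Hazard ratio of non-first classes versus the first class
#'   (`> 0`).
#' @param baseline_hazard Hazard of the first class (events per time unit).
#' @param censor_rate Expected censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A survival table (`sample_id`, `time`, `event`).
#' @export
survival_from_labels <- function(labels, hr = 3, baseline_hazard = 0.05,
                                 censor_rate = 0.2, seed = 1L) {
  if (hr <= 0) stop("hazard ratio must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censoring rate 1 leaves no events; need censor_rate in [0, 1)",
         call. = FALSE)
  }
  set.seed(seed)
  lam <- ifelse(labels == levels(labels)[1L], baseline_hazard,
                baseline_hazard * hr)
  t_event <- stats::rexp(length(labels), rate = lam)
  if (censor_rate > 0) {
    lam_c <- lam * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(length(labels), rate = lam_c)
  } else {
    t_cens <- rep(Inf, length(labels))
  }
  event <- as.integer(t_event <= t_cens)
  if (sum(event) == 0L) stop("no events in generated survival data",
                             call. = FALSE)
  survival_table(data.frame(sample_id = names(labels),
                            time = pmin(t_event, t_cens),
                            event = event, stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Emits the same delimited formats the readers consume (expression TSV,
#' label TSV, survival TSV when present) plus a machine-readable ground
#' truth JSON (`planted_pairs`, `batch`, `seed`), so recovery metrics can
#' be computed without re-deriving the plants.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- cohort_name(cohort$X)
  expr <- data.frame(gene = rownames(cohort$X), cohort$X,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, file.path(dir, paste0(nm, "_expression.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = names(cohort$labels),
                    class = as.character(cohort$labels))
  utils::write.table(lab, file.path(dir, paste0(nm, "_labels.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$survival)) {
    utils::write.table(cohort$survival,
                       file.path(dir, paste0(nm, "_survival.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(planted_pairs = cohort$truth,
                batch = cohort$batch[setdiff(names(cohort$batch),
                                             "gene_shift")],
                seed = cohort$seed)
  jsonlite::write_json(truth, file.path(dir, paste0(nm, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
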