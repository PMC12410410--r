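#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML (or an equivalent R list) with strict validation:
#' all problems are reported at once. Core fields: `seed` (mandatory),
#' `output_dir`, `cohorts` (list of `name` / `role` / `expression` path),
#' `labels` path, and the tuning knobs `a`, `x`, `classifier`, `cv`,
#' `prune`, plus flags `log_transform`, `stats_mode`, `fisher_alternative`,
#' `block_size`, and optional `whitelist`, `survival`, `signature`,
#' `class_order`, `simulate` sections.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `aigps_config` (defaults filled
#'   in).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  problems <- character(0)
  need <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  need(!is.null(config$seed) && is.numeric(config$seed),
       "seed is mandatory and must be numeric")
  need(!is.null(config$output_dir), "output_dir is required")
  if (!is.null(config$cohorts)) {
    for (i in seq_along(config$cohorts)) {
      co <- config$cohorts[[i]]
      need(!is.null(co$name), sprintf("cohorts[%d]: name missing", i))
      need(!is.null(co$expression),
           sprintf("cohorts[%d]: expression path missing", i))
      need(is.null(co$role) ||
             co$role %in% c("discovery", "training", "test"),
           sprintf("cohorts[%d]: role must be discovery/training/test", i))
    }
  }
  defaults <- list(a = NULL, x = 50L, classifier = "rf", cv = TRUE,
                   prune = FALSE, log_transform = FALSE,
                   stats_mode = "per-cohort",
                   fisher_alternative = "two.sided", block_size = 65536L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  need(config$classifier %in% c("rf", "knn", "lr", "svm", "mlp", "xgb", "nb"),
       "classifier must be one of rf/knn/lr/svm/mlp/xgb/nb")
  need(config$stats_mode %in% c("per-cohort", "frozen"),
       "stats_mode must be per-cohort or frozen")
  need(is.null(config$a) || all(config$a >= 0), "a must be >= 0")
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = c("aigps_config", "list"))
}

require_fields <- function(config, fields) {
  missing <- fields[vapply(fields, function(f) is.null(config[[f]]),
                           logical(1L))]
  if (length(missing) > 0L) {
    stop("configuration missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

load_config_data <- function(config, roles_needed = NULL) {
  require_fields(config, c("cohorts", "labels"))
  cohorts <- list()
  roles <- character(0)
  for (co in config$cohorts) {
    X <- read_expression(co$expression, co$name)
    if (isTRUE(config$log_transform)) {
      X0 <- log2(X + 1)
      attr(X0, "cohort_name") <- cohort_name(X)
      X <- X0
    }
    cohorts[[co$name]] <- X
    roles[co$name] <- if (is.null(co$role)) "test" else co$role
  }
  if (!is.null(roles_needed)) {
    for (r in roles_needed) {
      if (!r %in% roles) stop("no cohort with role '", r, "'", call. = FALSE)
    }
  }
  whitelist <- if (!is.null(config$whitelist)) read_gene_list(config$whitelist)
  cs <- intersect_genes(cohorts, whitelist = whitelist, roles = roles)
  labels <- read_labels(config$labels,
                        class_order = unlist(config$class_order))
  surv <- if (!is.null(config$survival)) read_survival(config$survival)
  list(cohorts = cs, labels = labels, survival = surv)
}

default_a <- function(config, labels) {
  if (!is.null(config$a)) return(config$a[1L])
  if (nlevels(labels) == 2L) 2 else 0
}

write_provenance <- function(config, dir) {
  prov <- list(package = "aigps",
               version = as.character(utils::packageVersion("aigps")),
               seed = config$seed,
               config = unclass(config))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

out_dir <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  config$output_dir
}

#' Pipeline subcommands
#'
#' Each subcommand validates its configuration, runs the corresponding
#' pipeline stage through the package's exported functions, writes its
#' outputs (plus a `provenance.json` echoing the config, package version and
#' seed) into `output_dir`, and returns its main result invisibly. Runs are
#' reproducible byte-for-byte from `(config, seed)`.
#'
#' * `cmd_simulate`: generate synthetic cohorts (section `simulate`: any
#'   [synthetic_spec()] field plus `n_cohorts`) and write them to disk.
#' * `cmd_screen`: rank all gene pairs on the discovery cohort(s) and write
#'   `screen_report.tsv`.
#' * `cmd_train`: read a screen report (`pairs` field), select the top `x`
#'   pairs, train on the training cohort(s), optionally prune
#'   zero-importance pairs, and write `signature.json`.
#' * `cmd_evaluate`: evaluate a signature (`signature` field) on every test
#'   cohort and pooled; writes per-cohort metrics and per-sample
#'   predictions.
#' * `cmd_survival`: odds-split all cohort samples on the signature's
#'   predicted response probability and write Kaplan-Meier curves and
#'   log-rank/Cox statistics.
#' * `cmd_network`: build the signature's gene-pair network on the first
#'   cohort and write GraphML and edge-list exports.
#'
#' @param config A config (path, list, or `aigps_config`); see
#'   [read_run_config()].
#' @return The stage's main result, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(config) {
  config <- read_run_config(config)
  dir <- out_dir(config)
  sim <- config$simulate
  if (is.null(sim)) sim <- list()
  # YAML 1.1 resolves a bare key `n` to boolean FALSE; repair it and accept
  # the unambiguous alias n_samples
  names(sim)[names(sim) == "FALSE"] <- "n"
  names(sim)[names(sim) == "n_samples"] <- "n"
  n_cohorts <- if (is.null(sim$n_cohorts)) 3L else as.integer(sim$n_cohorts)
  sim$n_cohorts <- NULL
  spec <- do.call(synthetic_spec, sim)
  cohorts <- generate_cohorts(spec, n_cohorts = n_cohorts, seed = config$seed)
  for (co in cohorts) write_synthetic_cohort(co, dir)
  labs <- do.call(rbind, lapply(cohorts, function(co) {
    data.frame(sample_id = names(co$labels), class = as.character(co$labels))
  }))
  utils::write.table(labs, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(config, dir)
  invisible(cohorts)
}

#' @rdname pipeline
#' @export
cmd_screen <- function(config) {
  config <- read_run_config(config)
  dir <- out_dir(config)
  data <- load_config_data(config, roles_needed = "discovery")
  roles <- data$cohorts$roles
  disc <- names(roles)[roles == "discovery"]
  Xd <- do.call(cbind, unname(data$cohorts$cohorts[disc]))
  a <- default_a(config, data$labels)
  scr <- screen_cohort(Xd, data$labels, a,
                       alternative = config$fisher_alternative,
                       fdr = TRUE, block_size = config$block_size)
  write_screen_file(scr, file.path(dir, "screen_report.tsv"))
  write_provenance(config, dir)
  invisible(scr)
}

#' Screen-report file round trip
#'
#' The report is a TSV preceded by one header comment line recording the
#' adaptive coefficient and test used, so downstream stages can detect a
#' coefficient mismatch.
#'
#' @param scr An `aigps_screen`.
#' @param path File path.
#' @export
write_screen_file <- function(scr, path) {
  con <- file(path, "w")
  writeLines(sprintf("# aigps screen a=%s test=%s", format(attr(scr, "a")),
                     attr(scr, "test")), con)
  utils::write.table(as.data.frame(scr), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_screen_file
#' @export
read_screen_file <- function(path) {
  if (!file.exists(path)) stop("screen report not found: ", path,
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  a <- NA_real_
  if (grepl("^# aigps screen", header)) {
    a <- as.numeric(sub(".*a=([0-9.eE+-]+).*", "\\1", header))
  }
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  attr(tab, "a") <- a
  tab
}

#' @rdname pipeline
#' @export
cmd_train <- function(config) {
  config <- read_run_config(config)
  dir <- out_dir(config)
  require_fields(config, "pairs")
  data <- load_config_data(config, roles_needed = "training")
  pairs <- read_screen_file(config$pairs)
  a_report <- attr(pairs, "a")
  a <- default_a(config, data$labels)
  if (!is.na(a_report) && !is.null(config$a) && a_report != config$a[1L] &&
      !isTRUE(config$override_a)) {
    stop("adaptive coefficient mismatch: screen report used a = ", a_report,
         " but config requests a = ", config$a[1L],
         "; set override_a: true to force the config value", call. = FALSE)
  }
  if (is.null(config$a) && !is.na(a_report)) a <- a_report
  top <- pairs[seq_len(min(config$x, nrow(pairs))), , drop = FALSE]
  roles <- data$cohorts$roles
  trn <- names(roles)[roles == "training"]
  Xt <- do.call(cbind, unname(data$cohorts$cohorts[trn]))
  sig <- train_signature(Xt, data$labels, top, a,
                         method = config$classifier, seed = config$seed,
                         cv = isTRUE(config$cv), prune = isTRUE(config$prune))
  write_signature(sig, file.path(dir, "signature.json"))
  write_provenance(config, dir)
  invisible(sig)
}

#' @rdname pipeline
#' @export
cmd_evaluate <- function(config) {
  config <- read_run_config(config)
  dir <- out_dir(config)
  require_fields(config, "signature")
  data <- load_config_data(config, roles_needed = "test")
  sig <- read_signature(config$signature)
  roles <- data$cohorts$roles
  tst <- names(roles)[roles == "test"]
  results <- list()
  pred_rows <- list()
  eval_cohort <- function(X, nm) {
    prob <- predict_cohort(sig, X, stats_mode = config$stats_mode)
    y <- droplevels(data$labels[colnames(X)])
    pred <- colnames(prob)[max.col(prob, ties.method = "first")]
    pred_rows[[nm]] <<- data.frame(cohort = nm, sample_id = rownames(prob),
                                   true = as.character(y), predicted = pred,
                                   prob, check.names = FALSE,
                                   stringsAsFactors = FALSE)
    if (length(sig$class_order) == 2L) {
      if (nlevels(y) < 2L) {
        warning("cohort '", nm, "': one class absent, AUC skipped",
                call. = FALSE)
        return(list(cohort = nm, auc = NA_real_))
      }
      list(cohort = nm, auc = auc(prob[, sig$class_order[1L]], y))
    } else {
      m <- multiclass_metrics(as.character(y), pred, sig$class_order)
      c(list(cohort = nm), m[c("accuracy", "macro_precision", "macro_recall",
                               "macro_f1", "weighted_precision",
                               "weighted_recall", "weighted_f1")])
    }
  }
  for (nm in tst) results[[nm]] <- eval_cohort(data$cohorts$cohorts[[nm]], nm)
  if (length(tst) > 1L) {
    Xp <- do.call(cbind, unname(data$cohorts$cohorts[tst]))
    attr(Xp, "cohort_name") <- "pooled"
    results[["pooled"]] <- eval_cohort(Xp, "pooled")
  }
  jsonlite::write_json(results, file.path(dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  preds <- do.call(rbind, pred_rows)
  utils::write.table(preds, file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_provenance(config, dir)
  invisible(results)
}

#' @rdname pipeline
#' @export
cmd_survival <- function(config) {
  config <- read_run_config(config)
  dir <- out_dir(config)
  require_fields(config, c("signature", "survival"))
  data <- load_config_data(config)
  sig <- read_signature(config$signature)
  X <- do.call(cbind, unname(data$cohorts$cohorts))
  keep <- colnames(X) %in% data$survival$sample_id
  if (!any(keep)) {
    stop("no cohort sample has survival data", call. = FALSE)
  }
  X <- X[, keep, drop = FALSE]
  attr(X, "cohort_name") <- "combined"
  prob <- predict_cohort(sig, X, stats_mode = config$stats_mode)
  p_resp <- stats::setNames(prob[, sig$class_order[1L]], rownames(prob))
  assignment <- risk_split(p_resp)
  km <- km_logrank(assignment, data$survival)
  cox <- cox_hr(assignment, data$survival)
  write_km_curves(km$km, file.path(dir, "km_curves.tsv"))
  jsonlite::write_json(list(logrank_p = km$p_value,
                            logrank_statistic = km$statistic,
                            hazard_ratio = cox$hazard_ratio,
                            ci_lower = cox$ci_lower,
                            ci_upper = cox$ci_upper,
                            n_low = cox$n_low, n_high = cox$n_high),
                       file.path(dir, "survival_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(assignment),
                     file.path(dir, "risk_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, dir)
  invisible(list(km = km, cox = cox, assignment = assignment))
}

#' @rdname pipeline
#' @export
cmd_network <- function(config) {
  config <- read_run_config(config)
  dir <- out_dir(config)
  require_fields(config, "signature")
  data <- load_config_data(config)
  sig <- read_signature(config$signature)
  X <- data$cohorts$cohorts[[1L]]
  graph <- build_network(sig, X, data$labels)
  write_network(graph, file.path(dir, "network.graphml"), "graphml")
  write_network(graph, file.path(dir, "network_edges.tsv"), "edgelist")
  write_provenance(config, dir)
  invisible(graph)
}
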