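## End-to-end orchestration: run configuration, the full
## divergence -> expression -> model -> classification -> bias -> ortholog
## pipeline over files on disk, and the fast table-only reproduction path.

read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(
    lapply(kv, function(x) paste(x[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1)
  )
}

#' Pipeline run configuration
#'
#' Paths to the pipeline inputs plus the analysis thresholds. Round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param input_dir directory holding `cds.fa`, `pep.fa`, `pairs.tsv`,
#'   `expression.tsv`, `annotations.tsv`, `triplets.tsv` and the triplet
#'   FASTA files (the layout [simulate_dataset()] writes).
#' @param out_dir output directory.
#' @param min_identity,min_coverage,max_ks pair filters.
#' @param fpr false-positive rate for threshold calibration.
#' @param yates apply the continuity correction in 2x2 chi-squared tests.
#' @param n_boot bootstrap resamples for trend support.
#' @param aligned_orthologs the triplet CDS files are already in codon
#'   correspondence (skip protein alignment in the branch stage).
#' @param seed seed for all stochastic stages.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir, out_dir,
                       min_identity = 0.30, min_coverage = 0.50, max_ks = 3.0,
                       fpr = 0.05, yates = TRUE, n_boot = 100,
                       aligned_orthologs = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  writeLines(
    vapply(names(config), function(k) {
      paste0(k, "=", format(config[[k]], digits = 17))
    }, character(1)),
    path
  )
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  kv <- read_key_values(path)
  num <- c("min_identity", "min_coverage", "max_ks", "fpr")
  int <- c("n_boot", "seed")
  cfg <- lapply(names(kv), function(k) {
    if (k %in% num) {
      as.numeric(kv[[k]])
    } else if (k %in% int) {
      as.integer(kv[[k]])
    } else if (k %in% c("yates", "aligned_orthologs")) {
      as.logical(kv[[k]])
    } else {
      kv[[k]]
    }
  })
  structure(stats::setNames(cfg, names(kv)), class = "run_config")
}

read_fasta_seqs <- function(path, type = "DNA") {
  set <- if (type == "DNA") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Run the full analysis pipeline over an input directory
#'
#' Stages: sequence divergence (align, NG86, filter), expression features,
#' model fitting and threshold calibration on the labelled pairs,
#' classification of all pairs, functional-bias report, and ortholog
#' retention/selection analysis with bootstrap trend support. Outputs (TSVs,
#' the model file and a key-value manifest with per-stage row counts) are
#' written under `config$out_dir`; the same objects are returned invisibly.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `divergence`, `filtered`, `features`,
#'   `model`, `calls`, `bias`, `retention`, `branches`, `selection`,
#'   `bootstrap`, `manifest`.
#' @export
run_full_pipeline <- function(config) {
  ind <- config$input_dir
  needed <- c("cds.fa", "pep.fa", "pairs.tsv", "expression.tsv",
              "annotations.tsv", "triplets.tsv")
  missing <- needed[!file.exists(file.path(ind, needed))]
  if (length(missing) > 0) {
    stop("missing pipeline input(s): ", paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    val
  }
  manifest <- list(seed = config$seed, fpr = config$fpr,
                   min_identity = config$min_identity,
                   min_coverage = config$min_coverage, max_ks = config$max_ks)

  records <- stage("read", read_gene_records(file.path(ind, "cds.fa"),
                                             file.path(ind, "pep.fa")))
  pairs <- utils::read.delim(file.path(ind, "pairs.tsv"),
                             stringsAsFactors = FALSE)
  divergence <- stage("divergence", pair_divergence(pairs, records))
  filtered <- stage("filter", filter_pairs(
    divergence, config$min_identity, config$min_coverage, config$max_ks
  ))
  manifest$n_pairs_in <- nrow(pairs)
  manifest$n_kept <- nrow(filtered$kept)
  manifest$n_rejected <- nrow(filtered$rejected)

  mat <- read_expression_matrix(file.path(ind, "expression.tsv"))
  feats <- stage("features", build_features(filtered$kept, mat))
  manifest$n_features <- nrow(feats$features)
  manifest$n_excluded_features <- nrow(feats$excluded)

  labelled <- feats$features[feats$features$label %in% c("high", "low"), ,
                             drop = FALSE]
  model <- stage("train", {
    m <- fit_dfd(labelled)
    calibrate_thresholds(m, labelled, fpr = config$fpr)
  })
  calls <- stage("classify", classify_pairs(model, feats$features))
  cnt <- attr(calls, "counts")
  manifest$n_high <- cnt[["high"]]
  manifest$n_low <- cnt[["low"]]
  manifest$n_unclassified <- cnt[["unclassified"]]
  manifest$roc_auc <- roc_auc(dfd_score(model, labelled), labelled$label)
  manifest$pr_auc <- pr_auc(dfd_score(model, labelled), labelled$label)
  manifest$thr_low <- model$thr_low
  manifest$thr_high <- model$thr_high

  annotations <- read_annotations(file.path(ind, "annotations.tsv"))
  breadth <- expression_breadth(mat)
  pair_map <- feats$features[, c("pair", "gene_a", "gene_b")]
  if ("mechanism" %in% names(pairs)) {
    pair_map <- merge(
      pair_map, pairs[, c("gene_a", "gene_b", "mechanism")],
      by = c("gene_a", "gene_b")
    )
  }
  bias <- stage("bias", bias_report(calls, pair_map, annotations, breadth))

  triplets <- read_triplets(file.path(ind, "triplets.tsv"))
  retention <- stage("retention", retention_analysis(
    triplets[triplets$class %in% c("high", "low"), , drop = FALSE]
  ))
  seqs <- list(
    at = read_fasta_seqs(file.path(ind, "triplet_cds_at.fa")),
    al = read_fasta_seqs(file.path(ind, "triplet_cds_al.fa")),
    br = read_fasta_seqs(file.path(ind, "triplet_cds_br.fa"))
  )
  branches <- stage("branches", triplet_branch_analysis(
    triplets, seqs, aligned = isTRUE(config$aligned_orthologs)
  ))
  singles <- branches[branches$class == "singleton", c("branch", "ka_ks")]
  dup_branches <- branches[branches$class %in% c("high", "low"), , drop = FALSE]
  selection <- stage("selection",
                     selection_proportions(dup_branches, singletons = singles))
  boot <- stage("bootstrap", bootstrap_support(
    triplets[triplets$class %in% c("high", "low"), , drop = FALSE],
    function(d) {
      r <- stats::aggregate(!is.na(d$al_gene), list(class = d$class), mean)
      r$x[r$class == "low"] > r$x[r$class == "high"]
    },
    n_boot = config$n_boot, seed = config$seed
  ))
  manifest$bootstrap_retention_support <- boot

  ## persist outputs
  od <- config$out_dir
  utils::write.table(divergence, file.path(od, "divergence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(filtered$rejected, file.path(od, "rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(feats$features, file.path(od, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(od, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(retention, file.path(od, "retention.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(branches, file.path(od, "branches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(selection, file.path(od, "selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_dfd_model(model, file.path(od, "model.txt"))
  writeLines(
    vapply(names(manifest), function(k) {
      paste0(k, "=", format(manifest[[k]], digits = 15))
    }, character(1)),
    file.path(od, "manifest.txt")
  )

  invisible(list(
    divergence = divergence, filtered = filtered, features = feats,
    model = model, calls = calls, bias = bias, retention = retention,
    branches = branches, selection = selection, bootstrap = boot,
    manifest = manifest
  ))
}

#' Fit and evaluate the DFD model from a precomputed feature table
#'
#' The fast reproduction path: given a table that already carries `ka_ks`,
#' `re_ks` and a high/low `label` (e.g. a published per-pair table), fit the
#' logistic model, calibrate thresholds at `fpr`, and evaluate ROC/PR AUC and
#' the cross-validated threshold stability.
#'
#' @param features data.frame with columns `ka_ks`, `re_ks`, `label`.
#' @param fpr false-positive rate for calibration.
#' @param n_cv cross-validation rounds (0 to skip).
#' @param seed RNG seed for the cross-validation splits.
#' @return list with `model`, `roc_auc`, `pr_auc`, `thr_low`, `thr_high`,
#'   `cv` (the [cross_validate()] output or `NULL`).
#' @export
paper_mode <- function(features, fpr = 0.05, n_cv = 100, seed = 1L) {
  req <- c("ka_ks", "re_ks", "label")
  if (!all(req %in% names(features))) {
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  }
  model <- fit_dfd(features)
  model <- calibrate_thresholds(model, features, fpr = fpr)
  s <- dfd_score(model, features)
  cv <- if (n_cv > 0) {
    cross_validate(features, n_rounds = n_cv, fpr = fpr, seed = seed)
  }
  list(
    model = model,
    roc_auc = roc_auc(s, features$label),
    pr_auc = pr_auc(s, features$label),
    thr_low = model$thr_low, thr_high = model$thr_high,
    cv = cv
  )
}
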