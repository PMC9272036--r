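#' Read a genotype dosage matrix
#'
#' Supports two tab-delimited dialects. `"raw"` follows the PLINK
#' `--recode A` layout: six leading metadata columns (FID, IID, PAT, MAT,
#' SEX, PHENOTYPE) followed by one dosage column per variant, with allele
#' suffixes in the header (`rs123_A`) stripped to the variant name.
#' `"matrix"` is a plain numeric matrix with a header, optionally with a
#' leading non-numeric sample-id column. `"auto"` picks `"raw"` when the
#' header starts with FID and IID.
#'
#' @param path File path.
#' @param dialect `"auto"`, `"raw"` or `"matrix"`.
#' @return A list with `dosages` (numeric matrix), `sample_ids`, `snp_ids`,
#'   and `missing` (logical flag per sample: any missing dosage).
#' @export
read_genotypes <- function(path, dialect = c("auto", "raw", "matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  if (dialect == "auto")
    dialect <- if (ncol(dt) >= 6L &&
                   identical(toupper(names(dt)[1:2]), c("FID", "IID")))
      "raw" else "matrix"
  if (dialect == "raw") {
    if (ncol(dt) < 7L)
      stop("raw dialect needs 6 metadata columns plus dosages",
           call. = FALSE)
    ids <- as.character(dt[[2L]])
    dos <- dt[, -(1:6), drop = FALSE]
    snp <- sub("_[A-Za-z0-9]+$", "", names(dos))
  } else {
    first_chr <- !is.numeric(dt[[1L]])
    ids <- if (first_chr) as.character(dt[[1L]]) else
      as.character(seq_len(nrow(dt)))
    dos <- if (first_chr) dt[, -1L, drop = FALSE] else dt
    snp <- names(dos)
  }
  bad <- names(dos)[!vapply(dos, is.numeric, logical(1))]
  if (length(bad) > 0L)
    stop("non-numeric dosage column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  M <- as.matrix(dos)
  colnames(M) <- snp
  rownames(M) <- ids
  list(dosages = M, sample_ids = ids, snp_ids = snp,
       missing = rowSums(is.na(M)) > 0L)
}

#' Read exposure and outcome phenotypes
#'
#' Reads a tab-delimited phenotype table with named columns and returns the
#' exposure and outcome vectors, optionally re-aligned to a vector of
#' genotype sample ids (by the IID or first column). Samples present in
#' only one of the two sources are dropped with a warning.
#'
#' @param path File path.
#' @param exposure_col,outcome_col Column names.
#' @param sample_ids Optional genotype sample ids to align to.
#' @return A list with `exposure`, `outcome`, `sample_ids`, and
#'   `n_complete` (complete cases over the two phenotypes).
#' @export
read_phenotypes <- function(path, exposure_col, outcome_col,
                            sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  for (col in c(exposure_col, outcome_col))
    if (!col %in% names(dt))
      stop("column '", col, "' not found; available: ",
           paste(names(dt), collapse = ", "), call. = FALSE)
  id_col <- if ("IID" %in% names(dt)) "IID" else names(dt)[1L]
  ids <- as.character(dt[[id_col]])
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    extra <- setdiff(ids, sample_ids)
    if (length(extra) > 0L)
      warning(length(extra), " phenotype sample(s) absent from genotypes ",
              "dropped", call. = FALSE)
    idx <- match(sample_ids, ids)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " genotype sample(s) missing phenotypes ",
              "dropped", call. = FALSE)
    }
    keep <- !is.na(idx)
    dt <- dt[idx[keep], , drop = FALSE]
    ids <- sample_ids[keep]
  }
  exposure <- dt[[exposure_col]]
  outcome <- dt[[outcome_col]]
  n_complete <- sum(stats::complete.cases(exposure, outcome))
  message(n_complete, " complete cases over exposure and outcome")
  list(exposure = exposure, outcome = outcome, sample_ids = ids,
       n_complete = n_complete)
}

#' Write a simulated dataset to disk
#'
#' Emits three files under `prefix`: a PLINK-raw-style tab-delimited
#' genotype file (`<prefix>.raw`; FID IID PAT MAT SEX PHENOTYPE then one
#' standardized dosage column per variant), a two-phenotype table
#' (`<prefix>.pheno.tsv` with IID, exposure, outcome), and a YAML truth
#' file (`<prefix>.truth.yaml`) echoing the settings, allele frequencies
#' and true genetic effects. Numbers are written with 17 significant
#' digits so dosages round-trip bitwise through [read_genotypes()].
#'
#' @param dataset A `polymr_sim` object.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  if (!inherits(dataset, "polymr_sim"))
    stop("`dataset` must be a polymr_sim object", call. = FALSE)
  n <- nrow(dataset$genotypes)
  m <- ncol(dataset$genotypes)
  ids <- paste0("id", seq_len(n))
  snps <- paste0("snp", seq_len(m), "_A")

  raw_path <- paste0(prefix, ".raw")
  gmat <- matrix(fmt_num(dataset$genotypes), n, m)
  meta <- cbind(FID = ids, IID = ids, PAT = "0", MAT = "0", SEX = "0",
                PHENOTYPE = "-9")
  utils::write.table(cbind(meta, gmat), raw_path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c(colnames(meta), snps))

  pheno_path <- paste0(prefix, ".pheno.tsv")
  utils::write.table(
    data.frame(IID = ids, exposure = fmt_num(dataset$exposure),
               outcome = fmt_num(dataset$outcome)),
    pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_path <- paste0(prefix, ".truth.yaml")
  st <- dataset$settings
  yaml::write_yaml(list(
    settings = list(n_samples = st$n_samples,
                    n_causal_snps = st$n_causal_snps,
                    heritability = st$heritability, q_x = st$q_x,
                    q_y = st$q_y, q_y2 = st$q_y2,
                    gwas_p_threshold = st$gwas_p_threshold,
                    seed = st$seed),
    causal_function = list(family = st$causal_function$family,
                           coefficients = st$causal_function$coefficients,
                           scale = st$causal_function$scale,
                           steepness = st$causal_function$steepness),
    mafs = dataset$mafs, true_beta = dataset$true_beta), truth_path, precision = 15)
  invisible(c(raw = raw_path, pheno = pheno_path, truth = truth_path))
}

#' Write a fit report and curve table
#'
#' Emits a coefficient table (`<prefix>.coefficients.tsv`: term, order,
#' type, estimate, SE, p), the coefficient covariance matrix
#' (`<prefix>.vcov.tsv`), the causal curve (`<prefix>.curve.tsv`: grid,
#' estimate, lower, upper), and a YAML summary
#' (`<prefix>.summary.yaml`: non-linearity p, causally explained variance,
#' log likelihoods, sample and instrument counts, selection trace). Output
#' is deterministic given the fit and curve.
#'
#' @param fit A [polymr()] fit.
#' @param curve A `polymr_curve` from [predict.polymr()]; computed with
#'   default settings if missing (seeded for determinism).
#' @param prefix Output path prefix.
#' @return The file paths, invisibly.
#' @export
write_report <- function(fit, curve = NULL, prefix) {
  if (!inherits(fit, "polymr"))
    stop("`fit` must be a polymr object", call. = FALSE)
  if (is.null(curve))
    curve <- stats::predict(fit, seed = 1L)
  terms <- names(fit$coefficients)
  type <- ifelse(terms == "(Intercept)", "intercept",
                 ifelse(startsWith(terms, "x^"), "exposure",
                        "control_function"))
  ord <- integer(length(terms))
  ord[type != "intercept"] <-
    as.integer(sub("^[^^]*\\^", "", terms[type != "intercept"]))
  coef_path <- paste0(prefix, ".coefficients.tsv")
  utils::write.table(
    data.frame(term = terms, order = ord, type = type,
               estimate = fmt_num(fit$coefficients),
               se = fmt_num(fit$se), p = fmt_num(fit$pvalues)),
    coef_path, sep = "\t", quote = FALSE, row.names = FALSE)

  vcov_path <- paste0(prefix, ".vcov.tsv")
  vm <- matrix(fmt_num(fit$vcov), nrow(fit$vcov),
               dimnames = list(NULL, colnames(fit$vcov)))
  utils::write.table(cbind(term = terms, vm), vcov_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  curve_path <- paste0(prefix, ".curve.tsv")
  utils::write.table(
    data.frame(grid = fmt_num(curve$grid),
               estimate = fmt_num(curve$estimate),
               lower = fmt_num(curve$lower),
               upper = fmt_num(curve$upper)),
    curve_path, sep = "\t", quote = FALSE, row.names = FALSE)

  summary_path <- paste0(prefix, ".summary.yaml")
  yaml::write_yaml(list(
    n = fit$n, n_dropped = fit$n_dropped,
    instruments = list(supplied = fit$iv$n_initial, used = fit$iv$n_used,
                       reverse_filter = fit$iv$reverse_filter),
    k = fit$k, l = fit$l,
    retained_exposure_orders = fit$k_retained,
    retained_cf_orders = fit$l_retained,
    nonlinearity_p = fit$nonlinearity_p,
    causal_r2 = fit$causal_r2,
    loglik_full = fit$loglik_full, loglik_linear = fit$loglik_linear,
    selection_trace = lapply(fit$selection_trace, function(t)
      list(order = t$order, p = t$p))), summary_path, precision = 15)
  invisible(c(coefficients = coef_path, vcov = vcov_path,
              curve = curve_path, summary = summary_path))
}

#' Read back a written coefficient table
#'
#' @param path Path to a `.coefficients.tsv` written by [write_report()].
#' @return A data frame with numeric estimate/se/p columns.
#' @export
read_report <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  dt$estimate <- as.numeric(dt$estimate)
  dt$se <- as.numeric(dt$se)
  dt$p <- as.numeric(dt$p)
  dt
}

#' Read simulation settings from a YAML config file
#'
#' The file holds the flat [polymr_settings()] fields plus an optional
#' `causal_function` block (`family`, `coefficients`, `scale`,
#' `steepness`), or a single `preset` key naming a scenario from
#' [polymr_scenarios()] with optional field overrides.
#'
#' @param path YAML file path.
#' @return A `polymr_settings` object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset
  cfg$preset <- NULL
  cf <- cfg$causal_function
  cfg$causal_function <- NULL
  if (!is.null(cf))
    cfg$causal_function <- causal_fun(
      family = cf$family %||% "polynomial",
      coefficients = cf$coefficients,
      scale = cf$scale %||% 0.1, steepness = cf$steepness %||% 1)
  if (!is.null(preset))
    do.call(polymr_scenarios, c(list(scenario = preset), cfg))
  else
    do.call(polymr_settings, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
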