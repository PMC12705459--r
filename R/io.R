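#' @section File formats:
#' All tabular interchange is TSV, UTF-8, '.' decimal, header row
#' mandatory. Matrices are written with named columns (and a leading
#' row-name column where rows are meaningful). TE tensors are exchanged as
#' tidy long TSVs (subject_id, region, from_state, to_state, energy) from
#' which the N x k x k arrays are reconstructed exactly.
#' @name stateTE-io
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read a numeric matrix as TSV
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  write_tsv(as.data.frame(m), path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in ", path)
  m
}

#' Write / read a parcellation TSV (region_id, region_name, network)
#' @param parc a [parcellation()].
#' @param path file path.
#' @export
write_parcellation <- function(parc, path) {
  write_tsv(as.data.frame(parc), path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- read_tsv(path)
  need <- c("region_id", "region_name", "network")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("parcellation file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  parcellation(df$network, df$region_name)
}

#' Write a synthetic cohort to disk
#'
#' One series TSV per subject (frames x regions, header = region names), a
#' manifest TSV (subject_id, path, covariates), the connectome, the
#' parcellation, and the ground-truth frame labels.
#'
#' @param cohort output of [generate_cohort()].
#' @param sc the connectome matrix.
#' @param parc the [parcellation()].
#' @param out_dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, sc, parc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  series_dir <- file.path(out_dir, "series")
  dir.create(series_dir, showWarnings = FALSE)
  paths <- vapply(cohort$series, function(s) {
    p <- file.path(series_dir, paste0(s$subject_id, ".tsv"))
    m <- s$data
    colnames(m) <- parc$region_name
    write_tsv(as.data.frame(m), p)
    p
  }, character(1))
  manifest <- cbind(data.frame(subject_id = cohort$covariates$subject_id,
                               path = paths, stringsAsFactors = FALSE),
                    cohort$covariates[, setdiff(names(cohort$covariates),
                                                "subject_id")])
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  write_matrix_tsv(sc, file.path(out_dir, "connectome.tsv"))
  write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
  lab <- data.frame(
    subject_id = rep(vapply(cohort$series, `[[`, character(1),
                            "subject_id"),
                     times = lengths(cohort$labels)),
    frame = unlist(lapply(cohort$labels, seq_along)),
    state = unlist(cohort$labels))
  write_tsv(lab, file.path(out_dir, "true_labels.tsv"))
  invisible(file.path(out_dir, "manifest.tsv"))
}

#' Read a cohort manifest and its series files
#'
#' Validates required columns, unique subject ids, and that every series
#' file shares the same region count (matching the parcellation when
#' given). Series are loaded eagerly into memory at spec scale (86 regions)
#' but through an accessor that checks dimensions per file.
#'
#' @param path manifest TSV (columns `subject_id`, `path`, covariates).
#' @param parc optional [parcellation()] for dimension checks.
#' @return list with `series` (list of `subject_id` + `data`) and
#'   `covariates` (data.frame).
#' @export
read_manifest <- function(path, parc = NULL) {
  man <- read_tsv(path)
  need <- c("subject_id", "path")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0L)
    stop("manifest ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(man$subject_id))
    stop("duplicate subject_id in manifest: ",
         man$subject_id[duplicated(man$subject_id)][1L])
  base <- dirname(path)
  series <- vector("list", nrow(man))
  n_regions <- if (!is.null(parc)) nrow(parc) else NULL
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) stop("series file not found: ", man$path[i])
    m <- as.matrix(read_tsv(p))
    if (!is.numeric(m))
      stop("non-numeric cell in series file ", p)
    if (is.null(n_regions)) n_regions <- ncol(m)
    if (ncol(m) != n_regions)
      stop("series file ", p, " has ", ncol(m),
           " regions; expected ", n_regions)
    series[[i]] <- list(subject_id = man$subject_id[i],
                        data = unname(m))
  }
  cov <- man[, setdiff(names(man), "path"), drop = FALSE]
  list(series = series, covariates = cov)
}

#' Write / read a regional TE tensor as a tidy long TSV
#'
#' Columns: subject_id, region (1-based), from_state, to_state, energy.
#'
#' @param tensor N x k x k array.
#' @param subject_id subject identifier.
#' @param path file path; `read_te_tensor` returns a list of tensors keyed
#'   by subject id.
#' @param append append to an existing file (for multi-subject bundles).
#' @export
write_te_tensor <- function(tensor, subject_id, path, append = FALSE) {
  d <- dim(tensor)
  df <- data.frame(subject_id = subject_id,
                   region = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
                   from_state = rep(rep(seq_len(d[2L]), each = d[1L]),
                                    times = d[3L]),
                   to_state = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
                   energy = as.vector(tensor))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append,
                     append = append)
  invisible(path)
}

#' @rdname write_te_tensor
#' @export
read_te_tensor <- function(path) {
  df <- read_tsv(path)
  need <- c("subject_id", "region", "from_state", "to_state", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("TE file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$subject_id), function(d) {
    n <- max(d$region); k <- max(d$from_state)
    tensor <- array(NA_real_, dim = c(n, k, k))
    tensor[cbind(d$region, d$from_state, d$to_state)] <- d$energy
    tensor
  })
  out[unique(df$subject_id)]
}
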