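#' Read one connectivity file
#'
#' Accepts either a square numeric matrix (comma- or tab-delimited text,
#' optional header row and leading label column) or a 3-column edge list
#' (`node_i, node_j, weight`; nodes as 1-based integers or shared labels).
#' The format is inferred from the shape unless given explicitly.
#'
#' @param file path to the file.
#' @param format `"auto"`, `"matrix"`, or `"edge_list"`.
#' @param n_nodes required for unlabelled edge lists whose largest index
#'   understates the vertex count; otherwise inferred.
#' @return A numeric matrix (raw values; pass through
#'   [prepare_connectivity()] to obtain a graph).
#' @export
read_connectivity_matrix <- function(file, format = c("auto", "matrix", "edge_list"),
                                     n_nodes = NULL) {
  format <- match.arg(format)
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(file, sep = sep, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_num <- function(x) suppressWarnings(as.numeric(x))
  # header row: fields beyond the first are non-numeric in row 1 only
  header <- nrow(raw) > 1 && any(is.na(as_num(unlist(raw[1, -1])))) &&
    !any(is.na(as_num(unlist(raw[2, -1]))))
  labels <- NULL
  if (header) {
    labels <- as.character(unlist(raw[1, ], use.names = FALSE))
    raw <- raw[-1, , drop = FALSE]
  }
  if (format == "auto") {
    format <- if (ncol(raw) == 3 && nrow(raw) != 3 && !header) "edge_list" else "matrix"
  }
  if (format == "edge_list") {
    i_raw <- raw[[1]]; j_raw <- raw[[2]]
    w <- as_num(raw[[3]])
    if (any(is.na(w))) stop("edge list weights are not numeric in ", file, call. = FALSE)
    if (!any(is.na(as_num(i_raw))) && !any(is.na(as_num(j_raw)))) {
      i <- as.integer(as_num(i_raw)); j <- as.integer(as_num(j_raw))
      n <- max(i, j, n_nodes %||% 0L)
      labs <- NULL
    } else {
      labs <- sort(unique(c(i_raw, j_raw)))
      i <- match(i_raw, labs); j <- match(j_raw, labs)
      n <- length(labs)
    }
    M <- matrix(0, n, n, dimnames = if (is.null(labs)) NULL else list(labs, labs))
    M[cbind(i, j)] <- w
    M[cbind(j, i)] <- w
    return(M)
  }
  # matrix form: strip a leading label column when its fields are non-numeric
  if (any(is.na(as_num(raw[[1]])))) {
    if (is.null(labels)) labels <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
    if (header) labels <- labels[-1]
  }
  M <- matrix(as_num(as.matrix(raw)), nrow = nrow(raw))
  if (any(is.na(M))) stop("non-numeric entries in connectivity file ", file, call. = FALSE)
  if (nrow(M) != ncol(M)) {
    stop("connectivity matrix in ", file, " is not square (",
         nrow(M), " x ", ncol(M), ")", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) == nrow(M)) dimnames(M) <- list(labels, labels)
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a directory of per-subject connectivity files
#'
#' One file per subject; the file stem becomes the subject id and subjects
#' are ordered lexicographically (deterministic across platforms).  All
#' matrices must share dimensions, and any vertex labels must agree.
#'
#' @param path directory containing `.csv`/`.tsv`/`.txt` files.
#' @param format passed to [read_connectivity_matrix()].
#' @param fisher_z,negative_mode passed to [prepare_connectivity()].
#' @return Named list of [weighted_graph()]s, sorted by subject id.
#' @export
read_connectivity_dir <- function(path, format = "auto", fisher_z = FALSE,
                                  negative_mode = "zero") {
  files <- sort(list.files(path, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE))
  if (!length(files)) stop("no connectivity files found in ", path, call. = FALSE)
  ids <- sub("\\.[^.]+$", "", basename(files))
  mats <- lapply(files, read_connectivity_matrix, format = format)
  dims <- vapply(mats, nrow, 1L)
  if (length(unique(dims)) != 1) {
    off <- files[dims != stats::median(dims)]
    stop("connectivity dimension mismatch in: ", paste(basename(off), collapse = ", "),
         call. = FALSE)
  }
  lab_sets <- unique(lapply(mats, rownames))
  lab_sets <- lab_sets[!vapply(lab_sets, is.null, TRUE)]
  if (length(lab_sets) > 1) {
    stop("vertex labels differ across connectivity files in ", path, call. = FALSE)
  }
  graphs <- lapply(mats, prepare_connectivity, fisher_z = fisher_z,
                   negative_mode = negative_mode)
  names(graphs) <- ids
  graphs
}

#' Read a phenotype table
#'
#' CSV with columns `subject_id`, `outcome` (0/1), then covariates.
#'
#' @param file path to the CSV.
#' @param covariates character vector of covariate columns to include.
#' @param subject_ids optional id vector to reorder/validate against (e.g.
#'   names of the graphs read from a directory).
#' @return A [phenotype_design()].
#' @export
read_phenotype <- function(file, covariates = character(), subject_ids = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = TRUE)
  if (!all(c("subject_id", "outcome") %in% names(tab))) {
    stop("phenotype table must have columns subject_id and outcome", call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (!is.null(subject_ids)) {
    missing <- setdiff(subject_ids, tab$subject_id)
    if (length(missing)) {
      stop("phenotype table is missing subjects: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tab <- tab[match(subject_ids, tab$subject_id), , drop = FALSE]
  }
  phenotype_design(tab, outcome = "outcome", covariates = covariates,
                   id = "subject_id")
}

#' Write / read a distance matrix as CSV with subject ids
#'
#' @param D symmetric distance matrix with subject ids as dimnames.
#' @param path output CSV path.
#' @return `write_distance_matrix` invisibly returns `path`;
#'   `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(D, path) {
  ids <- rownames(D) %||% sprintf("S%03d", seq_len(nrow(D)))
  df <- data.frame(subject_id = ids,
                   format(D, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("subject_id", ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df$subject_id)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  dimnames(M) <- list(ids, ids)
  M
}

#' Serialise a result object to JSON (with provenance)
#'
#' Writes score-test or experiment results as JSON at full double precision.
#' Non-finite values anywhere in the payload are an error: results must be
#' computable or absent, never silently NaN.  A provenance block records the
#' seed, distance-norm order where applicable, and the package version.
#'
#' @param result an `rpd_score_test` or `rpd_experiment`.
#' @param path output path (`.json`); a companion `.csv` with the grid or
#'   per-iteration records is written next to it.
#' @param seed seed to record in the provenance block.
#' @return Invisibly, the JSON path.
#' @export
write_result <- function(result, path, seed = NULL) {
  if (inherits(result, "rpd_score_test")) {
    payload <- list(
      p_upper = result$p_upper, p_raw = result$p_raw, M = result$M, W = result$W,
      L = result$L, U = result$U,
      grid = result$grid$rho, S = result$grid$S, Q = result$grid$Q,
      muQ = result$grid$mu_Q, sigmaQ = result$grid$sigma_Q,
      p_norm_order = result$p_norm_order, n = result$n
    )
    companion <- result$grid
  } else if (inherits(result, "rpd_experiment")) {
    payload <- list(
      name = result$name, iterations = result$iterations,
      summary = result$summary
    )
    companion <- result$records
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  num <- unlist(payload[vapply(payload, is.numeric, TRUE)], use.names = FALSE)
  if (any(!is.finite(num))) {
    stop("refusing to serialise non-finite values in result", call. = FALSE)
  }
  payload$provenance <- list(
    seed = seed %||% result$seed,
    package = "rpdkernel",
    version = as.character(utils::packageVersion("rpdkernel")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  csv_path <- sub("\\.json$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  utils::write.csv(companion, csv_path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' One weight-matrix CSV per subject under `subjects/` (file stem = subject
#' id), a cohort manifest `manifest.csv` (subject_id, group), and a JSON
#' provenance record with the full generator specification.
#'
#' @param cohort an `rpd_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rpd_cohort"))
  dir.create(file.path(dir, "subjects"), showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$graphs)) {
    w <- cohort$graphs[[id]]$weights
    utils::write.table(
      format(w, digits = 17, scientific = TRUE, trim = TRUE),
      file.path(dir, "subjects", paste0(id, ".csv")),
      sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE
    )
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(
    c(unclass(spec), list(package = "rpdkernel",
                          version = as.character(utils::packageVersion("rpdkernel")))),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
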