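# Numeric serialization uses 17 significant digits so that write/read
# round-trips reproduce doubles exactly.
num17 <- function(x) sprintf("%.17g", x)

read_tsv_checked <- function(path, expect_cols = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stopf("%s: empty file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1]])
  bad <- which(vapply(fields, length, 1L) != n_col)
  if (length(bad)) {
    stopf("%s: parse error at line %d (expected %d fields, found %d)",
      path, bad[1], n_col, length(fields[[bad[1]]]))
  }
  if (!is.null(expect_cols) && n_col != expect_cols) {
    stopf("%s: expected %d columns, found %d", path, expect_cols, n_col)
  }
  fields
}

#' Write / read a parcellation as TSV
#'
#' Columns `node_id`, `label`, `x_mm`, `y_mm`, `z_mm`, `network` with a
#' header row.
#'
#' @param parc A parcellation.
#' @param path File path.
#' @return `read_parcellation` returns a `parcellation` data.frame.
#' @export
write_parcellation <- function(parc, path) {
  out <- data.frame(
    node_id = parc$node_id, label = parc$label,
    x_mm = num17(parc$x_mm), y_mm = num17(parc$y_mm),
    z_mm = num17(parc$z_mm), network = parc$network
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  fields <- read_tsv_checked(path, expect_cols = 6)
  hdr <- fields[[1]]
  want <- c("node_id", "label", "x_mm", "y_mm", "z_mm", "network")
  if (!identical(hdr, want)) {
    stopf("%s: header must be %s", path, paste(want, collapse = ", "))
  }
  body <- fields[-1]
  parc <- data.frame(
    node_id = as.integer(vapply(body, `[[`, "", 1)),
    label = vapply(body, `[[`, "", 2),
    x_mm = as.numeric(vapply(body, `[[`, "", 3)),
    y_mm = as.numeric(vapply(body, `[[`, "", 4)),
    z_mm = as.numeric(vapply(body, `[[`, "", 5)),
    network = vapply(body, `[[`, "", 6),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(parc[, c("x_mm", "y_mm", "z_mm")])))) {
    stopf("%s: non-finite coordinates", path)
  }
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' Write / read a numeric matrix as TSV
#'
#' No header; rows are nodes (or channels), columns timepoints. Values are
#' serialized at 17 significant digits for exact round-trips.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(num17(r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  fields <- read_tsv_checked(path)
  do.call(rbind, lapply(fields, as.numeric))
}

#' Write / read a connectivity matrix with its JSON sidecar
#'
#' The K x K Fisher-z matrix goes to `<path>` as TSV and subject metadata
#' (`subject_id`, `group`) to `<path>.json`.
#'
#' @param C A `connectivity_matrix`.
#' @param path File path for the TSV.
#' @return `read_connectivity` returns a `connectivity_matrix`.
#' @export
write_connectivity <- function(C, path) {
  write_matrix_tsv(C$z, path)
  jsonlite::write_json(
    list(subject_id = C$subject_id, group = C$group, K = nrow(C$z)),
    paste0(path, ".json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  z <- read_matrix_tsv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path)
  } else {
    list(subject_id = NA_character_, group = NA_character_)
  }
  structure(
    list(
      z = z,
      subject_id = if (is.null(meta$subject_id)) NA_character_ else
        meta$subject_id,
      group = if (is.null(meta$group)) NA_character_ else meta$group
    ),
    class = "connectivity_matrix"
  )
}

#' Write / read a thresholded graph as a sparse edge list
#'
#' TSV columns `i`, `j`, `weight` (upper triangle only) preceded by a
#' comment line holding a JSON header with `K` and `density`.
#'
#' @param g A `thresholded_graph`.
#' @param path File path.
#' @return `read_edge_list` returns a `thresholded_graph`.
#' @export
write_edge_list <- function(g, path) {
  ut <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  hdr <- jsonlite::toJSON(
    list(K = g$K, density = g$density), auto_unbox = TRUE, digits = NA
  )
  lines <- c(
    paste0("#", hdr), "i\tj\tweight",
    sprintf("%d\t%d\t%s", ut[, 1], ut[, 2],
      num17(g$weights[ut]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#")) {
    stopf("%s: parse error at line 1 (missing JSON header)", path)
  }
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  body <- lines[-(1:2)]
  weights <- matrix(0, meta$K, meta$K)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 3)
    if (length(bad)) {
      stopf("%s: parse error at line %d", path, bad[1] + 2)
    }
    i <- as.integer(vapply(parts, `[[`, "", 1))
    j <- as.integer(vapply(parts, `[[`, "", 2))
    w <- as.numeric(vapply(parts, `[[`, "", 3))
    weights[cbind(i, j)] <- w
    weights[cbind(j, i)] <- w
  }
  structure(
    list(
      weights = weights, density = meta$density, K = meta$K,
      subject_id = NA_character_, group = NA_character_
    ),
    class = "thresholded_graph"
  )
}

#' Write / read a synthetic cohort directory
#'
#' Per-subject time-series and confound TSVs, the parcellation TSV and a
#' JSON manifest mapping subject id to group and file paths.
#'
#' @param cohort A [simulate_cohort()] cohort.
#' @param dir Output directory (created if needed).
#' @return `read_cohort` returns a `cohort` (without the generator spec).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  entries <- lapply(cohort$subjects, function(s) {
    ts_file <- paste0(s$subject_id, "_timeseries.tsv")
    cf_file <- paste0(s$subject_id, "_confounds.tsv")
    write_matrix_tsv(s$timeseries, file.path(dir, ts_file))
    write_matrix_tsv(s$confounds, file.path(dir, cf_file))
    list(
      subject_id = s$subject_id, group = s$group,
      timeseries = ts_file, confounds = cf_file
    )
  })
  jsonlite::write_json(
    list(
      parcellation = "parcellation.tsv", tr_s = cohort$tr_s,
      subjects = entries
    ),
    file.path(dir, "cohort.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"))
  parc <- read_parcellation(file.path(dir, manifest$parcellation))
  subjects <- lapply(manifest$subjects, function(e) {
    ts <- read_matrix_tsv(file.path(dir, e$timeseries))
    rownames(ts) <- parc$label
    structure(
      list(
        subject_id = e$subject_id, group = e$group, timeseries = ts,
        confounds = {
          cf <- read_matrix_tsv(file.path(dir, e$confounds))
          if (nrow(cf) == 9) {
            rownames(cf) <- c("global", "wm", "csf", paste0("motion", 1:6))
          }
          cf
        },
        tr_s = manifest$tr_s
      ),
      class = "subject_record"
    )
  })
  structure(
    list(
      parcellation = parc, subjects = subjects,
      groups = factor(
        vapply(subjects, `[[`, "", "group"),
        levels = GROUP_LEVELS
      ),
      tr_s = manifest$tr_s
    ),
    class = "cohort"
  )
}
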