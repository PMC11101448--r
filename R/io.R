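# File formats: trial tables (CSV), labeled RDMs (CSV), fitted-object
# serialization to directories of CSV + JSON.

#' Read a trial-response table
#'
#' Expects UTF-8 comma-separated text with a header and columns
#' `participant_id`, `trial_id`, `stimulus_id`, `label_1` (required) and
#' `label_2`, `label_3` (optional; empty cells allowed beyond `label_1`).
#' Rows without a first label are rejected with their line numbers; any
#' `label_4`-style column is a schema error (at most 3 labels per trial).
#'
#' @param path CSV file path.
#' @return A tibble of validated trial responses; rejected rows are reported
#'   in a warning and recorded in the `rejected` attribute.
#' @export
load_trials <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(tbl) == 0) {
    warn("Trial file is empty.")
    return(tibble(participant_id = character(), trial_id = character(),
                  stimulus_id = character(), label_1 = character(),
                  label_2 = character(), label_3 = character()))
  }
  required <- c("participant_id", "trial_id", "stimulus_id", "label_1")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  extra_labels <- grep("^label_[0-9]+$", names(tbl), value = TRUE)
  over <- extra_labels[as.integer(sub("label_", "", extra_labels)) > 3]
  if (length(over) > 0) {
    abort(sprintf("At most 3 labels per trial: offending column(s) %s",
                  paste(over, collapse = ", ")))
  }
  for (col in c("label_2", "label_3")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  bad <- which(is.na(tbl$label_1) | !nzchar(tbl$label_1))
  if (length(bad) > 0) {
    warn(sprintf("Rejected %d row(s) without a first label (data line %s).",
                 length(bad), paste(head(bad, 10), collapse = ", ")))
    tbl <- tbl[-bad, , drop = FALSE]
  }
  out <- dplyr::select(tbl, dplyr::all_of(c(required, "label_2", "label_3")))
  attr(out, "rejected") <- bad
  out
}

#' @rdname load_trials
#' @param trials A trial tibble.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path, na = "")
  invisible(path)
}

#' Read / write a labeled RDM as CSV
#'
#' The CSV stores the square distance matrix with labels as both header and
#' first column.
#'
#' @param path CSV path.
#' @return An `rdm` object.
#' @export
load_rdm <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  labels <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1])
  if (nrow(m) != ncol(m) || !identical(labels, colnames(m))) {
    abort("RDM file must be square with matching row and column labels.")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  structure(list(distances = m, labels = labels), class = "rdm")
}

#' @rdname load_rdm
#' @param rdm An `rdm` object.
#' @export
write_rdm <- function(rdm, path) {
  m <- as_rdm_matrix(rdm)
  out <- dplyr::bind_cols(tibble(label = rownames(m)), as_tibble(m))
  readr::write_csv(out, path)
  invisible(path)
}

#' Serialize a fitted visual-semantic map to a directory
#'
#' Writes the coefficient matrix and both PCA models as CSV plus a JSON
#' metadata file, all plain text. [read_concept_map()] restores the object
#' exactly (up to numeric printing precision, 17 significant digits).
#'
#' @param map A `visual_semantic_map`.
#' @param dir Output directory (created if needed).
#' @export
write_concept_map <- function(map, dir) {
  stopifnot(inherits(map, "visual_semantic_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_csv <- function(m, f) {
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(dir, f), sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  write_num_csv(map$B, "B.csv")
  for (side in c("visual", "semantic")) {
    p <- map[[paste0(side, "_pca")]]
    write_num_csv(p$rotation, paste0(side, "_rotation.csv"))
    write_num_csv(rbind(p$mean), paste0(side, "_mean.csv"))
    write_num_csv(rbind(p$sdev), paste0(side, "_sdev.csv"))
    write_num_csv(rbind(p$explained), paste0(side, "_explained.csv"))
  }
  meta <- list(
    t = map$t, provenance = map$provenance,
    visual = map$visual_pca[c("k", "d", "whiten", "variance_threshold")],
    semantic = map$semantic_pca[c("k", "d", "whiten", "variance_threshold")]
  )
  jsonlite::write_json(meta, file.path(dir, "map.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_concept_map
#' @export
read_concept_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "map.json"), simplifyVector = TRUE)
  read_num <- function(f) {
    as.matrix(utils::read.table(file.path(dir, f), sep = ",", header = FALSE))
  }
  mk_pca <- function(side) {
    info <- meta[[side]]
    structure(
      list(mean = as.numeric(read_num(paste0(side, "_mean.csv"))),
           rotation = unname(read_num(paste0(side, "_rotation.csv"))),
           sdev = as.numeric(read_num(paste0(side, "_sdev.csv"))),
           k = info$k,
           explained = as.numeric(read_num(paste0(side, "_explained.csv"))),
           variance_threshold = info$variance_threshold,
           whiten = info$whiten, d = info$d),
      class = "pca_model"
    )
  }
  structure(
    list(B = unname(read_num("B.csv")),
         visual_pca = mk_pca("visual"),
         semantic_pca = mk_pca("semantic"),
         t = meta$t,
         provenance = meta$provenance),
    class = "visual_semantic_map"
  )
}

#' Write an image as PNG
#'
#' @param image Array `h x w x 3` with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("The 'png' package is required to write PNG files.")
  }
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("The 'png' package is required to read PNG files.")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
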