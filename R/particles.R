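#' Construct / validate a particle table
#'
#' Per-subtomogram bookkeeping: pose (the alignment transform, see
#' [pose()]), provenance, score and class label. Stored on disk as a plain
#' TSV with fixed column names
#' `particle_id, motor_id, site_index, phi, theta, psi, dx, dy, dz, score,
#' class_label`; extra columns are preserved verbatim.
#'
#' @param df data.frame with at least `particle_id`; missing standard
#'   columns are filled with defaults (angles/shifts 0, score `NA`,
#'   class_label `"unset"`, site_index `NA`).
#' @return validated data.frame of class `particle_table`.
#' @export
particle_table <- function(df) {
  if (!is.data.frame(df)) stop("`df` must be a data.frame", call. = FALSE)
  if (!"particle_id" %in% names(df))
    stop("particle table needs a `particle_id` column", call. = FALSE)
  n <- nrow(df)
  defaults <- list(motor_id = as.character(df$particle_id),
                   site_index = rep(NA_integer_, n),
                   phi = 0, theta = 0, psi = 0,
                   dx = 0, dy = 0, dz = 0,
                   score = NA_real_, class_label = "unset")
  for (col in names(defaults))
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  df$particle_id <- as.character(df$particle_id)
  if (anyDuplicated(df$particle_id))
    stop("duplicate particle_id values", call. = FALSE)
  if (n > 0) {
    si <- df$site_index[!is.na(df$site_index)]
    if (length(si) && (any(si < 0) || any(si > 15)))
      stop("site_index must be in [0, 15]", call. = FALSE)
    bad <- setdiff(unique(df$class_label), c("occupied", "empty", "ambiguous", "unset"))
    if (length(bad))
      stop("invalid class_label value(s): ", paste(bad, collapse = ", "), call. = FALSE)
    for (col in c("phi", "theta", "psi"))
      df[[col]] <- normalize_angle(as.numeric(df[[col]]))
  }
  std <- c("particle_id", "motor_id", "site_index", "phi", "theta", "psi",
           "dx", "dy", "dz", "score", "class_label")
  df <- df[, c(std, setdiff(names(df), std)), drop = FALSE]
  class(df) <- c("particle_table", "data.frame")
  df
}

#' Read a particle table from TSV
#' @param path path to a tab-separated file with a header line.
#' @return a [particle_table()].
#' @export
read_particles <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if ("site_index" %in% names(df)) df$site_index <- as.integer(df$site_index)
  particle_table(df)
}

#' Write a particle table to TSV
#' @param table a [particle_table()] (or coercible data.frame).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_particles <- function(table, path) {
  table <- particle_table(as.data.frame(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Poses stored in a particle table
#' @param table a [particle_table()].
#' @return list of [pose()] objects, one per row.
#' @export
particle_poses <- function(table) {
  lapply(seq_len(nrow(table)), function(i)
    pose(c(table$phi[i], table$theta[i], table$psi[i]),
         c(table$dx[i], table$dy[i], table$dz[i])))
}
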