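# ---------------------------------------------------------------------------
# Per-shot sparse reflection lists: constructor and plain-text I/O.
# Stream format (one file, shots concatenated):
#   # shot <id> cell <a> <b> <c> <alpha> <beta> <gamma>
#   h k l I sigma
# ---------------------------------------------------------------------------

#' Construct a shot
#'
#' @param shot_id text identifier.
#' @param reflections data.frame with columns `h`, `k`, `l`, `I`, `sigma`;
#'   duplicate indices within a shot are forbidden.
#' @param cell optional length-6 unit cell.
#' @param true_operator optional integer ground-truth operator index
#'   (synthetic data only).
#' @return object of class `shot`.
#' @export
new_shot <- function(shot_id, reflections, cell = NULL,
                     true_operator = NA_integer_) {
  need <- c("h", "k", "l", "I", "sigma")
  if (!all(need %in% names(reflections))) {
    stop("shot reflections need columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(reflections$I))) stop("non-finite intensity")
  key <- paste(reflections$h, reflections$k, reflections$l)
  if (anyDuplicated(key)) stop("duplicate hkl within shot ", shot_id)
  structure(
    list(shot_id = as.character(shot_id), refl = reflections, cell = cell,
         true_operator = true_operator),
    class = "shot"
  )
}

#' @export
print.shot <- function(x, ...) {
  cat("shot", x$shot_id, "with", nrow(x$refl), "reflections\n")
  invisible(x)
}

#' Write shots to a concatenated plain-text stream
#' @param shots list of `shot` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shots <- function(shots, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (s in shots) {
    cell <- if (is.null(s$cell)) rep(0, 6) else s$cell
    writeLines(sprintf("# shot %s cell %.4f %.4f %.4f %.3f %.3f %.3f",
                       s$shot_id, cell[1], cell[2], cell[3], cell[4],
                       cell[5], cell[6]), con)
    writeLines(sprintf("%d %d %d %.6g %.6g", s$refl$h, s$refl$k, s$refl$l,
                       s$refl$I, s$refl$sigma), con)
  }
  invisible(path)
}

#' Read shots from a concatenated plain-text stream
#' @param path file written by [write_shots()].
#' @return list of `shot` objects.
#' @export
read_shots <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# shot ", lines)
  if (length(hdr) == 0L) stop("no shot headers in ", basename(path))
  ends <- c(hdr[-1L] - 1L, length(lines))
  shots <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    tok <- strsplit(trimws(lines[hdr[i]]), "\\s+")[[1L]]
    id <- tok[3L]
    cell <- as.numeric(tok[5:10])
    if (all(cell == 0)) cell <- NULL
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                ncol = 5L, byrow = TRUE)
    refl <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                       l = as.integer(m[, 3]), I = m[, 4], sigma = m[, 5])
    shots[[i]] <- new_shot(id, refl, cell = cell)
  }
  shots
}
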