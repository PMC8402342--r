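#' @keywords internal
"_PACKAGE"

# class labels used throughout; order fixed so probability columns line up
TRIAGE_CLASSES <- c("bacterial", "viral", "noninfected")

DIRECTION_CODES <- c("up_strong", "up", "down", "down_strong", "none")

# arrow glyphs accepted in manifests as synonyms for the direction codes
DIRECTION_GLYPHS <- local({
  x <- c("up_strong", "up", "down", "down_strong", "none")
  names(x) <- c("\u2191\u2191", "\u2191", "\u2193", "\u2193\u2193", "none")
  x
})

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_ps("'%s' must be a single number", name)
  if (x < min) stop_ps("'%s' must be >= %g (got %g)", name, min, x)
  invisible(x)
}

normalize_direction <- function(code) {
  code <- as.character(code)
  out <- ifelse(code %in% DIRECTION_CODES, code,
                unname(DIRECTION_GLYPHS[code]))
  out
}

as_class_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), TRIAGE_CLASSES)
  if (length(bad) > 0)
    stop_ps("unknown class label(s): %s (expected %s)",
            paste(bad, collapse = ", "), paste(TRIAGE_CLASSES, collapse = "/"))
  factor(labels, levels = TRIAGE_CLASSES)
}

# md5 of an in-memory object via its canonical JSON serialization
object_md5 <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             tf)
  unname(tools::md5sum(tf))
}
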