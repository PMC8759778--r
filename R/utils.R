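`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
.msgf  <- function(...) message(sprintf(...))

.checkEnum <- function(x, allowed, what) {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad))
    .stopf("unknown %s value(s): %s (allowed: %s)", what,
           paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  invisible(x)
}

## serialize/deserialize candidate->read-count maps ("TRBV9:9;TRBV5:1")
parseSupport <- function(s) {
  if (is.na(s) || !nzchar(s)) .stopf("empty support map")
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2)) .stopf("malformed support map: %s", s)
  val <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
  names(val) <- vapply(kv, `[`, "", 1)
  if (anyNA(val) || any(val <= 0))
    .stopf("support counts must be positive numbers: %s", s)
  val
}

formatSupport <- function(v) paste(names(v), v, sep = ":", collapse = ";")

## content hash for provenance manifests (md5 of serialized object)
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
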