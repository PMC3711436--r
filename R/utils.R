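# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Draw n sub-seeds (< 2^31) from the current RNG stream.
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

assert_dna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Coerce seeds/references given as a character vector, a seq record
# data.frame, a contig, or an assembly into a records data.frame (id, seq).
as_records <- function(x) {
  if (inherits(x, "read_pool")) return(x$records)
  if (inherits(x, "mito_assembly")) {
    return(data.frame(id = vapply(x$contigs, `[[`, "", "id"),
                      seq = vapply(x$contigs, `[[`, "", "seq"),
                      qual = NA_character_, stringsAsFactors = FALSE))
  }
  if (inherits(x, "mito_contig")) {
    return(data.frame(id = x$id, seq = x$seq, qual = NA_character_,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    if (is.null(x$qual)) x$qual <- NA_character_
    return(x[, c("id", "seq", "qual")])
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(data.frame(id = ids, seq = unname(toupper(x)), qual = NA_character_,
                      stringsAsFactors = FALSE))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as sequence records")
}
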