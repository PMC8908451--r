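# internal helpers shared across modules

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Replace non-finite values (NaN/Inf from degenerate statistics) by 0.
fin0 <- function(x) {
  x[!is.finite(x)] <- 0
  x
}

# canonical key for a protein set (order-free identity)
setKey <- function(members) paste(sort(members), collapse = "\t")

# read a two-column protein<TAB>term mapping into a named list of term sets
readMappingTSV <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\\s+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed mapping line ", bad[1L], ": expected 2 columns")
  }
  prot <- vapply(parts, `[`, "", 1L)
  term <- vapply(parts, `[`, "", 2L)
  lapply(split(term, prot), unique)
}
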