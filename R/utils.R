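## Internal helpers: seed substreams, deterministic evaluation, table output.

# Derive a reproducible per-stage seed from the master seed. Kept below 2^31
# so it is always a valid R integer seed.
substreamSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483647)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (base round() is round-half-even); every printed
# percentage in the workflow uses this convention.
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Tab-separated writer with a single '#' header comment declaring the
# generating stage and parameters, so every artifact is self-describing.
writeStageTable <- function(df, path, stage, params = NULL) {
  hdr <- paste0("# stage=", stage)
  if (!is.null(params) && length(params))
    hdr <- paste0(hdr, " ", paste(names(params), unlist(params),
                                  sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readStageTable <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
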