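# Gas constant, J/(mol K); temperatures enter thermodynamic formulas in
# kelvin (degC + 273.15) and nowhere else.
.RGAS <- 8.314
.KELVIN <- 273.15

# Run code with a local RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Encode/decode the ion map for flat-file sample sheets: "Na=140;K=5".
formatIons <- function(ions) {
  if (!length(ions)) return("")
  paste(sprintf("%s=%s", names(ions), format(unname(ions), trim = TRUE)),
        collapse = ";")
}

parseIons <- function(s) {
  if (is.na(s) || !nzchar(s)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad))
    stop("malformed ion field: ", s, call. = FALSE)
  setNames(as.numeric(vapply(kv, `[`, character(1), 2L)),
           vapply(kv, `[`, character(1), 1L))
}

# Human-readable condition label used to group screen records.
conditionLabel <- function(ph, ions) {
  ionStr <- if (is.character(ions)) ions else formatIons(ions)
  if (nzchar(ionStr)) sprintf("pH%s;%s", format(ph), ionStr)
  else sprintf("pH%s", format(ph))
}

# Ordered star scale shared by classification and ranking.
.STAR_LEVELS <- c("ns", "*", "**", "***", "****")

starRank <- function(stars) match(stars, .STAR_LEVELS)
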