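# Small internal helpers shared across modules.

invlogit <- function(eta) 1 / (1 + exp(-eta))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance between (x1,y1) and (x2,y2); inputs in meters.
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

stop_kc <- function(...) stop(..., call. = FALSE)

assert_cols <- function(df, cols, what) {
  found <- tolower(names(df))
  missing <- cols[!tolower(cols) %in% found]
  if (length(missing)) {
    stop_kc(
      sprintf(
        "%s: missing mandatory column(s) %s; expected %s; found %s",
        what,
        paste(missing, collapse = ", "),
        paste(cols, collapse = ", "),
        paste(names(df), collapse = ", ")
      )
    )
  }
  invisible(df)
}

# Coerce the accepted binary encodings ({1/0, TRUE/FALSE, Y/N, yes/no})
# to logical; anything else is an error naming the offending values.
coerce_binary <- function(x, field) {
  if (is.logical(x)) return(x)
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "TRUE", "T", "Y", "YES")] <- TRUE
  out[s %in% c("0", "FALSE", "F", "N", "NO")] <- FALSE
  bad <- !is.na(s) & s != "" & is.na(out)
  if (any(bad)) {
    stop_kc(sprintf(
      "field %s: unrecognised binary value(s): %s",
      field, paste(unique(s[bad]), collapse = ", ")
    ))
  }
  out
}
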