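# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
# seed = NULL means "use the ambient RNG stream".
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_irg <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "irgdose_error"))
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    stop_irg(what, " must be a data frame", class = "irgdose_bad_input")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_irg(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", "),
      class = "irgdose_bad_input"
    )
  }
  invisible(df)
}

check_status_tokens <- function(status) {
  bad <- setdiff(unique(status), c("active", "control"))
  if (length(bad) > 0) {
    stop_irg(
      "status must be 'active' or 'control'; found: ",
      paste(bad, collapse = ", "),
      class = "irgdose_bad_status"
    )
  }
  invisible(status)
}

check_activity_class <- function(activity_class) {
  bad <- setdiff(unique(activity_class), c("PDA", "NPDA"))
  if (length(bad) > 0) {
    stop_irg(
      "activity_class must be 'PDA' or 'NPDA'; found: ",
      paste(bad, collapse = ", "),
      class = "irgdose_bad_input"
    )
  }
  invisible(activity_class)
}

# cell key columns of an expert-score / consolidated-score table
CELL_COLS <- c(
  "setting", "intervention", "activity_class", "period",
  "domain", "declension"
)
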