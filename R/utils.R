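# Internal helpers shared across modules.

# Canonical biomarker and class vocabularies. Order matters: it fixes row
# order in area tables and the column order of effect tables.
snom_biomarkers <- function() c("lipids", "amide_I", "amide_II", "dna")

snom_classes <- function() {
  c("normal", "low_grade_dyskaryosis", "high_grade_dyskaryosis",
    "CIN2_HGCGIN", "adenocarcinoma_1B1")
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

stop_validation <- function(...) {
  stop(structure(
    class = c("snomchemo_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("snomchemo_format_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`", name, "` must be a single finite number")
  }
  if (strict && x <= lower) {
    stop_validation("`", name, "` must be > ", lower)
  }
  if (!strict && x < lower) {
    stop_validation("`", name, "` must be >= ", lower)
  }
  invisible(x)
}
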