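# deterministic uniform stream isolated from the caller's RNG state
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, globalenv())
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
}

# run `expr` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(expr)
}

# serialize a configuration list for provenance headers
config_json <- function(cfg) {
  as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

# write a data frame as CSV with provenance comment lines
write_csv_provenance <- function(df, path, cfg = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# hptsim; config: ", config_json(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
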