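`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically fans a single master seed out to per-stage seeds so that
#' independent pipeline stages (simulation, per-radius model fits, bootstrap)
#' draw from decorrelated streams while the whole run stays reproducible from
#' one integer.
#'
#' @param master integer master seed.
#' @param stage character tag naming the consuming stage (e.g. `"radius_30"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "radius_30")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps products exact in doubles
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  for (i in 1:3) h <- (h * 48271) %% m # Lehmer rounds to decorrelate
  as.integer(h %% (m - 1) + 1)
}

#' Write a JSON run manifest alongside an output
#' @param path file path for the manifest.
#' @param config named list of configuration values.
#' @param seed integer seed used.
#' @return invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(
    package = "spice",
    version = as.character(utils::packageVersion("spice")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# stop() with a class so tests can assert on specific failure modes
spice_error <- function(msg, class) {
  stop(structure(class = c(class, "spice_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
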