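#' Validate and complete a study configuration
#'
#' Fills a (possibly empty) key-value list with the default study design and
#' range-checks every field. The defaults mirror the reference design: 118
#' Tien Shan calls from 10 animals, 108 hybrid calls from 4 animals, 78 bank
#' calls from 5 animals, measured at 22050 Hz with a 512-point Hamming
#' spectrogram at 87.5% overlap, analysed over duration, 50% quartile and
#' entropy with 100 randomization replicates.
#'
#' Calls are allocated to animals as evenly as possible. A per-animal
#' allocation outside `calls_per_animal` (the field studies sampled 10-20
#' calls per animal) produces a warning, not an error: the reference hybrid
#' design itself (108 calls, 4 animals) cannot respect it.
#'
#' @param raw named list of overrides; unknown keys are an error.
#' @return object of class `run_config` (a completed, validated list).
#' @examples
#' cfg <- validate_config(list(n_calls = c(tien_shan = 30, hybrid = 20,
#'                                         bank = 20)))
#' cfg$n_calls
#' @export
validate_config <- function(raw = list()) {
  defaults <- list(
    n_calls = c(tien_shan = 118, hybrid = 108, bank = 78),
    n_individuals = c(tien_shan = 10, hybrid = 4, bank = 5),
    calls_per_animal = c(10, 20),
    sampling_rate_hz = 22050,
    fft_size = 512,
    overlap = 0.875,
    features = c("duration_s", "q50_hz", "entropy"),
    n_reps = 100,
    seed = 20190226,
    individual_effect_sd = 0,
    write_wav = FALSE,
    out_dir = NULL
  )
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop_volecall("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)

  groups <- c("tien_shan", "hybrid", "bank")
  for (key in c("n_calls", "n_individuals")) {
    v <- cfg[[key]]
    if (is.null(names(v))) names(v) <- groups
    if (!setequal(names(v), groups))
      stop_volecall(key, " must be named over ", paste(groups, collapse = ", "))
    if (any(v < 1) || any(v != round(v)))
      stop_volecall(key, " must hold positive integers")
    cfg[[key]] <- v[groups]
  }
  cpa <- cfg$calls_per_animal
  if (length(cpa) == 1L) cpa <- c(cpa, cpa)
  if (length(cpa) != 2L || any(cpa < 10) || any(cpa > 20) || cpa[1] > cpa[2])
    stop_volecall("calls_per_animal: allowed range is within [10, 20], got ",
                  paste(cfg$calls_per_animal, collapse = "-"))
  cfg$calls_per_animal <- cpa
  if (cfg$overlap < 0 || cfg$overlap >= 1)
    stop_volecall("overlap: must lie in [0, 1), got ", cfg$overlap)
  if (cfg$fft_size < 32 || log2(cfg$fft_size) %% 1 != 0)
    stop_volecall("fft_size: must be a power of two >= 32")
  if (cfg$sampling_rate_hz < 8000)
    stop_volecall("sampling_rate_hz: must be at least 8000")
  if (cfg$n_reps < 2) stop_volecall("n_reps: must be at least 2")
  if (cfg$individual_effect_sd < 0)
    stop_volecall("individual_effect_sd: must be nonnegative")
  if (!all(cfg$features %in% c("duration_s", "peak_hz", "q25_hz", "q50_hz",
                               "q75_hz", "entropy")))
    stop_volecall("features: unknown measurement column(s)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# Even allocation of n calls over k animals; warns when outside `range`.
allocate_calls <- function(n, k, range = c(10, 20), group = "") {
  base <- n %/% k
  counts <- rep(base, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  if (any(counts < range[1]) || any(counts > range[2]))
    warning(sprintf(
      "group '%s': %d calls over %d animals gives %d-%d calls per animal, outside [%d, %d]",
      group, n, k, min(counts), max(counts), range[1], range[2]),
      call. = FALSE)
  counts
}
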