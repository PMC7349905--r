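#' Write / read a kymograph as TSV
#'
#' Long format with columns `t`, `x`, `m`, `c`; round-trips through
#' [read_kymograph_tsv()].
#'
#' @param sim a `polar_sim`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kymograph_tsv <- function(sim, path) {
  write_tsv_exact(tidy(sim), path)
  invisible(path)
}

# serialize doubles with 17 significant digits so write -> read is bit-exact
write_tsv_exact <- function(df, path, append = FALSE) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_tsv(df, path, append = append, col_names = TRUE)
}

#' @rdname write_kymograph_tsv
#' @return For `read_kymograph_tsv`, a tibble with columns `t`, `x`, `m`, `c`.
#' @export
read_kymograph_tsv <- function(path) {
  read_tsv_exact(path)
}

# bit-exact numeric parsing: read as text, convert with R's correctly
# rounded strtod (vroom's fast parser can be off by one ulp)
read_tsv_exact <- function(path, comment = "") {
  df <- readr::read_tsv(path, comment = comment,
                        col_types = readr::cols(.default = readr::col_character()))
  dplyr::mutate(df, dplyr::across(dplyr::everything(), function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == (is.na(col) | col == "NA"))) num else col
  }))
}

#' Write the mass ledger as TSV
#'
#' Columns `t` and `n_bar` (mean total density at each saved time).
#'
#' @inheritParams write_kymograph_tsv
#' @export
write_mass_ledger_tsv <- function(sim, path) {
  write_tsv_exact(tibble::tibble(t = sim$times, n_bar = sim$n_bar_series), path)
  invisible(path)
}

#' Write a dispersion relation as TSV
#'
#' Columns `q`, `re_sigma`, `im_sigma`, `v_phase`; a leading comment line
#' records all parameters.
#'
#' @param disp a `dispersion_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dispersion_tsv <- function(disp, path) {
  sys <- disp$sys
  rx <- sys$reaction
  hdr <- sprintf(
    "# vf=%g Dm=%g Dc=%g L=%g n_bar=%g kon=%g kfb=%g koff=%g KD=%g m_star=%g c_star=%g",
    disp$vf, sys$Dm, sys$Dc, sys$L, disp$state$n_bar,
    rx$kon %||% NA, rx$kfb %||% NA, rx$koff %||% NA, rx$KD %||% NA,
    disp$state$m_star, disp$state$c_star)
  writeLines(hdr, path)
  write_tsv_exact(tidy(disp), path, append = TRUE)
  invisible(path)
}

#' @rdname write_dispersion_tsv
#' @return For `read_dispersion_tsv`, the mode table as a tibble.
#' @export
read_dispersion_tsv <- function(path) {
  read_tsv_exact(path, comment = "#")
}

#' Write a run manifest
#'
#' YAML file echoing every parameter needed to re-execute a run
#' bit-identically: system, flow and reaction parameters, simulation
#' settings, seed, advection scheme, and package version. Units are um and s
#' throughout.
#'
#' @param sim a `polar_sim`.
#' @param path output path.
#' @param extra optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sim, path, extra = list()) {
  sys <- sim$sys
  fl <- sys$flow
  rx <- sys$reaction
  manifest <- c(list(
    package = "polarflow",
    version = as.character(utils::packageVersion("polarflow")),
    units = list(length = "um", time = "s", concentration = "1/um"),
    system = list(Dm = sys$Dm, Dc = sys$Dc, L = sys$L, n_bar = sys$n_bar,
                  boundary = sys$boundary, N = sys$N),
    flow = list(kind = fl$kind, vf = fl$vf, vmax = fl$vmax, t0 = fl$t0),
    reaction = list(kon = rx$kon, kfb = rx$kfb, koff = rx$koff, KD = rx$KD),
    sim = list(t_start = min(sim$times), t_end = max(sim$times),
               n_saves = length(sim$times), scheme = sim$scheme,
               seed = sim$seed),
    mass_drift = mass_drift(sim)
  ), extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
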