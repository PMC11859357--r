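# File I/O: YAML skin-model configs and CSV tables with commented metadata
# headers ("# key: value" lines before the column header). Plain-text formats
# throughout so every input and result is inspectable.

#' Load a skin model from a YAML configuration
#'
#' Expects a `layers` list (name, kind, thickness_cm, C_B, C_H2O, g, n,
#' musp_a, musp_b) plus optional `superstrate` (n, thickness_cm) and
#' `ambient_n` entries. Every layer is validated through [skin_layer()], so
#' composition errors (e.g. C_B + C_H2O > 1) are reported with the offending
#' layer's name.
#'
#' @param path Path to the YAML file.
#' @return A [skin_model()].
#' @export
load_skin_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || !length(cfg$layers))
    stop("config has no `layers` entry: ", path, call. = FALSE)
  layers <- lapply(cfg$layers, function(e) {
    e <- fix_yaml_n_key(e)
    need <- c("name", "kind", "thickness_cm", "C_B", "C_H2O")
    miss <- setdiff(need, names(e))
    if (length(miss))
      stop("layer entry missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    skin_layer(name = e[["name"]], kind = e[["kind"]],
               thickness_cm = e[["thickness_cm"]],
               C_B = e[["C_B"]], C_H2O = e[["C_H2O"]],
               g = e[["g"]] %||% 0.9, n = e[["n"]] %||% 1.37,
               musp_a = e[["musp_a"]], musp_b = e[["musp_b"]])
  })
  sup <- fix_yaml_n_key(cfg$superstrate %||% list())
  skin_model(layers,
             superstrate_n = sup[["n"]] %||% 1.4,
             superstrate_thickness_cm = sup[["thickness_cm"]] %||% 0.02,
             ambient_n = cfg[["ambient_n"]] %||% 1.0)
}

#' Write a skin model to YAML
#'
#' Inverse of [load_skin_model()]; a round trip preserves all values.
#'
#' @param model A [skin_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skin_model <- function(model, path) {
  stopifnot(inherits(model, "skin_model"))
  cfg <- list(
    superstrate = list(n = model$superstrate_n,
                       thickness_cm = model$superstrate_thickness_cm),
    ambient_n = model$ambient_n,
    layers = lapply(unname(model$layers), function(l)
      l[c("name", "kind", "thickness_cm", "C_B", "C_H2O", "g", "n",
          "musp_a", "musp_b")]))
  # quote the refractive-index key: a bare `n:` is YAML 1.1 for FALSE
  txt <- gsub("(?m)^(\\s*)n:", "\\1\"n\":", yaml::as.yaml(cfg), perl = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' Load chromophore spectra from CSV
#'
#' Columns: `wavelength_nm`, `mu_a_water`, `mu_a_blood`, `mu_a_other`
#' (cm^-1). Lines starting with `#` are metadata and skipped.
#'
#' @param path Path to the CSV file.
#' @return A [chromophore_set()].
#' @export
load_spectra_csv <- function(path) {
  df <- read_csv_meta(path)$data
  need <- c("wavelength_nm", "mu_a_water", "mu_a_blood", "mu_a_other")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("spectra CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$wavelength_nm, strictly = TRUE))
    stop("spectra CSV wavelength grid must be strictly ascending",
         call. = FALSE)
  chromophore_set(df$wavelength_nm, df$mu_a_water, df$mu_a_blood,
                  df$mu_a_other)
}

#' Write a data.frame as CSV with a commented metadata header
#'
#' Metadata entries are written as leading `# key: value` lines so that the
#' file remains machine-readable while carrying its provenance (seed, config
#' hash, condition labels, ...).
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param meta Named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV with a commented metadata header
#'
#' @param path Path to the file.
#' @return List with `data` (data.frame) and `meta` (named character list
#'   parsed from leading `# key: value` lines).
#' @export
read_csv_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  hdr <- hdr[hdr == seq_along(hdr)]   # only the leading comment block
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  list(data = df, meta = meta)
}

#' Load an OGTT case from CSV
#'
#' Columns: `time_min`, `cg_mmol_per_L`, `ad_1550`; condition is taken from
#' the metadata header (`# condition: ...`) unless given.
#'
#' @param path Path to the case CSV.
#' @param condition Optional condition label overriding the file metadata.
#' @return An [ogtt_case()].
#' @export
load_ogtt_case <- function(path, condition = NULL) {
  r <- read_csv_meta(path)
  need <- c("time_min", "cg_mmol_per_L", "ad_1550")
  miss <- setdiff(need, names(r$data))
  if (length(miss))
    stop("OGTT CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cond <- condition %||% r$meta$condition %||% "unknown"
  ogtt_case(time = r$data$time_min, cg = r$data$cg_mmol_per_L,
            ad_1550 = r$data$ad_1550, condition = cond)
}

#' Write an OGTT case to CSV
#'
#' @param case An [ogtt_case()].
#' @param path Output path.
#' @param meta Extra metadata entries for the header.
#' @return `path`, invisibly.
#' @export
write_ogtt_case <- function(case, path, meta = list()) {
  stopifnot(inherits(case, "ogtt_case"))
  write_csv_meta(
    data.frame(time_min = case$time, cg_mmol_per_L = case$cg,
               ad_1550 = case$ad_1550),
    path, meta = c(list(condition = case$condition), meta))
}

#' Write a Monte Carlo result table to CSV
#'
#' Emits the per-ring detected weights with standard errors plus a metadata
#' header carrying the seed, photon budget and energy-budget closure.
#'
#' @param result An `mc_result` from [run_mc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mc_result <- function(result, path) {
  stopifnot(inherits(result, "mc_result"))
  write_csv_meta(result$detected, path,
                 meta = list(wavelength_nm = result$wavelength_nm,
                             n_photons = result$n_photons,
                             seed = result$seed,
                             budget_rel_error = result$budget_rel_error))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# yaml's 1.1 schema reads a bare `n:` mapping key as the boolean FALSE;
# restore it so configs written without quoting still load.
fix_yaml_n_key <- function(e) {
  hit <- names(e) %in% c("FALSE", "FALSE.")
  if (any(hit) && !"n" %in% names(e)) names(e)[which(hit)[1]] <- "n"
  e
}
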