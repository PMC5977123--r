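#' Write a radial dose kernel to a TSV table
#'
#' The format is tab-separated with `#`-prefixed metadata lines
#' (`diameter_nm`, `eta`, `exponent`) followed by a header and one row per
#' bin: `r_lo_nm`, `r_hi_nm`, `dose_gy_per_gy`. Values are written with
#' full double precision so a write/read round-trip is bit-identical.
#'
#' @param kernel A `radial_dose_kernel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kernel_table <- function(kernel, path) {
  stopifnot(inherits(kernel, "radial_dose_kernel"))
  cal <- kernel$calibration
  edges <- kernel$bin_edges_nm
  meta <- c(
    sprintf("# diameter_nm: %.17g", kernel$diameter_nm),
    sprintf("# eta: %.17g", cal$eta),
    sprintf("# exponent: %.17g", cal$exponent)
  )
  header <- "r_lo_nm\tr_hi_nm\tdose_gy_per_gy"
  rows <- sprintf(
    "%.17g\t%.17g\t%.17g",
    edges[-length(edges)], edges[-1], kernel$dose_gy_per_gy
  )
  writeLines(c(meta, header, rows), path)
  invisible(path)
}

#' Read a radial dose kernel from a TSV table
#'
#' Validates monotone bins, non-negative doses and the presence of the
#' metadata lines written by [write_kernel_table()]; errors name the
#' offending line.
#'
#' @param path Path to a kernel TSV.
#' @return A `radial_dose_kernel`.
#' @export
read_kernel_table <- function(path) {
  lines <- readLines(path)
  meta_idx <- grepl("^#", lines)
  meta <- parse_meta(lines[meta_idx])
  for (key in c("diameter_nm", "eta", "exponent")) {
    if (is.na(meta[key])) {
      abort(sprintf("Missing '# %s:' metadata line in %s.", key, path))
    }
  }
  body <- lines[!meta_idx]
  if (length(body) < 2 || body[1] != "r_lo_nm\tr_hi_nm\tdose_gy_per_gy") {
    abort("Expected header 'r_lo_nm\\tr_hi_nm\\tdose_gy_per_gy'.")
  }
  # parse as character, convert with base R: readr's fast double parser is
  # not correctly rounded in the last ulp, which would break bit-identical
  # round trips
  tab <- readr::read_tsv(
    I(body),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::everything(), as.numeric))
  line_no <- which(!meta_idx)[-1] # file line of each data row
  bad <- which(tab$r_lo_nm >= tab$r_hi_nm)
  if (length(bad) > 0) {
    abort(sprintf("Non-monotone radii (r_lo >= r_hi) at line %d.", line_no[bad[1]]))
  }
  bad <- which(diff(tab$r_lo_nm) <= 0 | tab$r_lo_nm[-1] != tab$r_hi_nm[-nrow(tab)])
  if (length(bad) > 0) {
    abort(sprintf("Bins not contiguous/increasing at line %d.", line_no[bad[1] + 1]))
  }
  bad <- which(tab$dose_gy_per_gy < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative dose at line %d.", line_no[bad[1]]))
  }
  rmax_um <- tab$r_hi_nm[nrow(tab)] / 1000
  cal <- kernel_calibration(
    eta = meta[["eta"]], exponent = meta[["exponent"]], r_max_um = rmax_um
  )
  new_radial_dose_kernel(
    meta[["diameter_nm"]],
    c(tab$r_lo_nm, tab$r_hi_nm[nrow(tab)]),
    tab$dose_gy_per_gy,
    cal
  )
}

parse_meta <- function(meta_lines) {
  out <- c(diameter_nm = NA_real_, eta = NA_real_, exponent = NA_real_)
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3 && m[2] %in% names(out)) {
      out[m[2]] <- as.numeric(m[3])
    }
  }
  out
}

#' Write and read GNP placement coordinate tables
#'
#' CSV with `#` metadata lines (`scenario`, `seed`, `diameter_nm`) and
#' columns `x_um`, `y_um`, `z_um`.
#'
#' @param placement A [sample_gnp_positions()] result.
#' @param path File path.
#' @return `write_placement_csv()` returns `path` invisibly;
#'   `read_placement_csv()` returns a `gnp_placement` tibble.
#' @export
write_placement_csv <- function(placement, path) {
  seed <- attr(placement, "seed")
  meta <- c(
    sprintf("# scenario: %s", attr(placement, "scenario") %||% "unknown"),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# diameter_nm: %.17g", attr(placement, "gnp_diameter_nm") %||% NA_real_)
  )
  rows <- sprintf(
    "%.17g,%.17g,%.17g",
    placement$x_um, placement$y_um, placement$z_um
  )
  writeLines(c(meta, "x_um,y_um,z_um", rows), path)
  invisible(path)
}

#' @rdname write_placement_csv
#' @export
read_placement_csv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grepl("^#", lines)
  meta <- lines[meta_idx]
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub("^#[^:]*:\\s*", "", hit[1])
  }
  # character + as.numeric for a correctly rounded (bit-identical) parse
  tab <- readr::read_csv(
    I(lines[!meta_idx]),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::everything(), as.numeric))
  seed <- suppressWarnings(as.integer(get("seed")))
  structure(
    as_tibble(tab),
    scenario = get("scenario"),
    seed = if (is.na(seed)) NULL else seed,
    gnp_diameter_nm = suppressWarnings(as.numeric(get("diameter_nm"))),
    class = c("gnp_placement", class(as_tibble(tab)))
  )
}

#' Read assay tables from CSV
#'
#' Thin validated readers for the package's tabular inputs: clonogenic
#' plate counts (`condition`, `cells_plated`, `colonies`, optional
#' `replicate`), per-nucleus focus counts (`nucleus_id`, `foci_count`,
#' `area_um2`) and per-sample uptake (`sample`, `au_mass_g_per_cell`,
#' `diameter_nm`).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_plates_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_plates(tab)
  as_tibble(tab)
}

#' @rdname read_plates_csv
#' @export
read_foci_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("foci_count", "area_um2") %in% names(tab))) {
    abort("Foci CSV needs columns `foci_count` and `area_um2`.")
  }
  as_tibble(tab)
}

#' @rdname read_plates_csv
#' @export
read_uptake_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("au_mass_g_per_cell", "diameter_nm") %in% names(tab))) {
    abort("Uptake CSV needs columns `au_mass_g_per_cell` and `diameter_nm`.")
  }
  as_tibble(tab)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
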