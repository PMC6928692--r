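# On-disk formats: two-column meridional profiles with '# key: value'
# headers, flat YAML configs with unit-suffixed keys, trace tables, and JSON
# run manifests.

#' Write and read meridional profiles
#'
#' Profiles are stored as two-column text tables (Z in 1/nm, intensity in
#' arbitrary units) at `%.8g` precision, preceded by a `# key: value` header
#' block carrying the metadata. Reading is a lossless round trip to that
#' precision; malformed rows are reported with their line numbers.
#'
#' @param profile a \linkS4class{MeridionalProfile}
#' @param path file path
#' @return `readProfile` returns the \linkS4class{MeridionalProfile}
#' @export
writeProfile <- function(profile, path) {
  md <- profile@metadata
  hdr <- c("# columns: Z_nm_inv intensity_au",
           vapply(names(md), function(k)
             sprintf("# %s: %s", k, paste(format(md[[k]]), collapse = ",")),
             character(1)))
  body <- sprintf("%.8g\t%.8g", profile@Z, profile@intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty profile file: ", path)
  isHdr <- startsWith(lines, "#")
  md <- list()
  for (l in lines[isHdr]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3 && m[2] != "columns") {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      lg <- if (val %in% c("TRUE", "FALSE")) as.logical(val) else NA
      md[[trimws(m[2])]] <- if (!is.na(num)) num else
        if (!is.na(lg)) lg else val
    }
  }
  body <- which(!isHdr & nzchar(trimws(lines)))
  if (!length(body)) stop("profile file has no data rows: ", path)
  parts <- strsplit(trimws(lines[body]), "\\s+")
  bad <- which(vapply(parts, function(p)
    length(p) != 2 || any(is.na(suppressWarnings(as.numeric(p)))), logical(1)))
  if (length(bad))
    stop("malformed profile rows at line(s): ",
         paste(body[bad], collapse = ", "))
  num <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  meridionalProfile(num[, 1], num[, 2], md)
}

# ---------------------------------------------------------------------------
# Flat YAML configuration with explicit units in key names
# ---------------------------------------------------------------------------

configKeyMap <- list(
  geometry = c(sarcomere_length_um = "sarcomereLength",
               thin_length_um = "thinLength", n_monomers = "nMonomers",
               monomer_spacing_s0_nm = "monomerSpacing",
               strand_half_period_nm = "strandHalfPeriod",
               thick_length_um = "thickLength", n_crowns = "nCrowns",
               crown_spacing_nm = "crownSpacing",
               heads_per_crown = "headsPerCrown", d10_sim_nm = "d10Sim",
               d10_slack_nm = "d10Slack",
               myofibril_occupancy = "myofibrilOccupancy",
               n_thick = "nThick"),
  elastic = c(Ka_pN = "Ka", Km_pN = "Km",
              kappa_xb_pN_per_nm = "kappaXb",
              titin_stiffness_pN_per_nm = "titinStiffness"),
  rates = c(dG_bind_kBT = "dGbind", dG_stroke_kBT = "dGstroke",
            k_bind_per_s = "kBind", k_adp0_per_s = "kAdp0",
            stroke_d_nm = "strokeD", delta2_nm = "delta2",
            k13_per_s = "k13", cap_k23_per_s = "capK23",
            cap_k32_per_s = "capK32", cap_k31_per_s = "capK31",
            kBT_pN_nm = "kBT", dt_s = "dt", binding_reach_nm = "bindingReach"))

#' Read a simulation configuration file
#'
#' Flat YAML with explicit units in the key names (e.g.
#' `monomer_spacing_s0_nm: 2.73`, `k_bind_per_s: 134`); unknown keys under
#' the run section (`duration_s`, `seed`, `beam_fwhm_nm_inv`, ...) are
#' returned verbatim in `$run`. Values given on the command line as
#' `--key=value` may be layered on top via `overrides`.
#'
#' @param path YAML file path
#' @param overrides named character or numeric vector of key overrides
#' @return list with `geometry` (\linkS4class{SarcomereGeometry}),
#'   `elastic`, `rates` and `run` (plain list)
#' @export
readSimConfig <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(overrides)) {
    for (k in names(overrides)) {
      v <- suppressWarnings(as.numeric(overrides[[k]]))
      raw[[k]] <- if (!is.na(v)) v else overrides[[k]]
    }
  }
  take <- function(section, ctor) {
    map <- configKeyMap[[section]]
    args <- list()
    for (k in names(map))
      if (!is.null(raw[[k]])) args[[map[[k]]]] <- raw[[k]]
    do.call(ctor, args)
  }
  known <- unlist(lapply(configKeyMap, names))
  list(geometry = take("geometry", sarcomereGeometry),
       elastic = take("elastic", elasticParams),
       rates = take("rates", rateParams),
       run = raw[setdiff(names(raw), known)])
}

#' @param config a list as returned by [readSimConfig()], or a list with
#'   any of `geometry`, `elastic`, `rates`, `run`
#' @rdname readSimConfig
#' @export
writeSimConfig <- function(config, path) {
  out <- list()
  for (section in names(configKeyMap)) {
    obj <- config[[section]]
    if (is.null(obj)) next
    map <- configKeyMap[[section]]
    for (k in names(map)) {
      v <- slot(obj, map[[k]])
      out[[k]] <- if (is.integer(v)) v else as.numeric(v)
    }
  }
  for (k in names(config$run)) out[[k]] <- config$run[[k]]
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Trace table and run manifest
# ---------------------------------------------------------------------------

#' Write a simulation trace as a long tabular text file
#'
#' Columns: `t_s`, `filament_id` (thick filament), `force_pN` (M-band
#' reaction), `n_state2`, `n_state3`.
#'
#' @param trace a \linkS4class{SimulationTrace}
#' @param path file path
#' @export
writeTrace <- function(trace, path) {
  nT <- length(trace@times); nF <- ncol(trace@thickForce)
  df <- data.frame(
    t_s = rep(trace@times, nF),
    filament_id = rep(seq_len(nF), each = nT),
    force_pN = as.vector(trace@thickForce),
    n_state2 = as.vector(trace@nState2),
    n_state3 = as.vector(trace@nState3))
  write.table(format(df, digits = 8, scientific = NA, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of a run: configuration snapshot, seed, timestamps, package
#' version and md5 digests of the input/output files.
#'
#' @param path output JSON path
#' @param config configuration list (as from [readSimConfig()])
#' @param seed integer seed
#' @param inputs,outputs character vectors of file paths to digest
#' @return the manifest list, invisibly
#' @export
writeManifest <- function(path, config, seed, inputs = character(),
                          outputs = character()) {
  snap <- list()
  for (section in intersect(names(config), names(configKeyMap))) {
    obj <- config[[section]]
    snap[[section]] <- sapply(slotNames(obj), function(s) slot(obj, s),
                              simplify = FALSE)
  }
  snap$run <- config$run
  digest <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  man <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package = "sarcoXray",
              version = as.character(packageVersion("sarcoXray")),
              seed = seed, config = snap,
              inputs = digest(inputs), outputs = digest(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}

# short content hash of a config+seed, used to name run directories
configHash <- function(config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeSimConfig(config, tmp)
  cat("seed:", seed, "\n", file = tmp, append = TRUE)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}
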