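# Dataset I/O --------------------------------------------------------------
#
# Two dialects:
#  * a Bruker-style directory: binary `ser` (interleaved real/imaginary
#    rows; little- or big-endian; int32 with an NC scaling exponent or
#    float64 per the DTYPA flag) plus JCAMP-like `acqus`/`acqu2s`
#    key-value text. Package-specific provenance (true log P, seed, echo
#    delay, slice plan, row order) travels in a `slogp_meta.json` sidecar;
#    reading works without it, falling back to positional row order with
#    a warning.
#  * a portable fixture: a self-describing JSON header (`*.slogp.json`)
#    next to a float64 little-endian payload (`*.slogp.bin`).

params_to_list <- function(p) {
  list(proton_freq = p$proton_freq, o1p = p$o1p, sweep_width = p$sweep_width,
       td = p$td, ns = p$ns, ds = p$ds, d1 = p$d1, tau = p$tau,
       noise_sigma = p$noise_sigma, seed = p$seed, nucleus = p$nuc$name)
}

list_to_params <- function(l) {
  acq_params(proton_freq = l$proton_freq, o1p = l$o1p,
             sweep_width = l$sweep_width, td = l$td, ns = l$ns, ds = l$ds,
             d1 = l$d1, tau = l$tau %||% 0, noise_sigma = l$noise_sigma %||% 0,
             seed = l$seed %||% 1L, nuc = nucleus(l$nucleus %||% "19F"))
}

plan_to_list <- function(plan) {
  if (is.null(plan)) return(NULL)
  list(nucleus = plan$nucleus$name, gradient_percent = plan$gradient$percent,
       g_max = plan$gradient$g_max, bandwidth = plan$bandwidth,
       proton_freq = plan$proton_freq,
       omega_hz = plan$offset_upper,
       coil_half_length = plan$coil_half_length,
       interface_clearance = plan$interface_clearance)
}

list_to_plan <- function(l) {
  if (is.null(l)) return(NULL)
  plan_slices(nucleus(l$nucleus %||% "19F"), proton_freq = l$proton_freq,
              gradient = gradient_spec(l$gradient_percent, l$g_max),
              bandwidth = l$bandwidth, omega = l$omega_hz, omega_unit = "Hz",
              coil_half_length = l$coil_half_length,
              interface_clearance = l$interface_clearance %||% 0)
}

interleave_rows <- function(rows) {
  unlist(lapply(rows, function(r) as.vector(rbind(Re(r), Im(r)))))
}

deinterleave <- function(vals, n_rows, td) {
  lapply(seq_len(n_rows), function(i) {
    row <- vals[((i - 1) * td + 1):(i * td)]
    complex(real = row[c(TRUE, FALSE)], imaginary = row[c(FALSE, TRUE)])
  })
}

#' Write a pseudo-2D dataset
#'
#' @param ds a `pseudo_spectrum2d`.
#' @param path target directory (Bruker dialect) or a `*.slogp.json` file
#'   path (fixture dialect).
#' @param dialect `"bruker"` or `"fixture"`; inferred from `path` when
#'   missing (a `.slogp.json` suffix selects the fixture).
#' @param dtype `"f8"` (float64, lossless, default) or `"i4"` (int32 with
#'   a stored NC scaling exponent), Bruker dialect only.
#' @param endian `"little"` (default) or `"big"`, Bruker dialect only.
#' @return the path, invisibly.
#' @export
write_dataset <- function(ds, path, dialect = NULL,
                          dtype = c("f8", "i4"), endian = c("little", "big")) {
  if (!inherits(ds, "pseudo_spectrum2d")) slogp_stop("ds must be a pseudo_spectrum2d")
  dtype <- match.arg(dtype)
  endian <- match.arg(endian)
  if (is.null(dialect))
    dialect <- if (grepl("\\.slogp\\.json$", path)) "fixture" else "bruker"
  switch(dialect,
         bruker = write_bruker(ds, path, dtype, endian),
         fixture = write_fixture(ds, path),
         slogp_stop(sprintf("unknown dialect '%s'", dialect)))
  invisible(path)
}

write_bruker <- function(ds, path, dtype, endian) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- ds$params
  vals <- interleave_rows(ds$rows)
  nc <- 0L
  if (dtype == "i4") {
    peak <- max(abs(vals), 1e-300)
    nc <- as.integer(ceiling(log2(peak / 2^28)))
    ints <- as.integer(round(vals / 2^nc))
    con <- file(file.path(path, "ser"), "wb")
    writeBin(ints, con, size = 4L, endian = endian)
    close(con)
  } else {
    con <- file(file.path(path, "ser"), "wb")
    writeBin(vals, con, size = 8L, endian = endian)
    close(con)
  }
  sfo1 <- p$bf1 * (1 + p$o1p * 1e-6)
  acqus <- c(
    "##TITLE= acquisition parameters",
    "##JCAMPDX= 5.0",
    "##ORIGIN= slicelogp",
    sprintf("##$BYTORDA= %d", if (endian == "big") 1L else 0L),
    sprintf("##$DTYPA= %d", if (dtype == "i4") 0L else 2L),
    sprintf("##$NC= %d", nc),
    sprintf("##$TD= %d", p$td),
    sprintf("##$SW_h= %.10g", p$sw_hz),
    sprintf("##$SFO1= %.10g", sfo1),
    sprintf("##$BF1= %.10g", p$bf1),
    sprintf("##$O1= %.10g", p$o1p * p$bf1),
    sprintf("##$NS= %d", p$ns),
    sprintf("##$DS= %d", p$ds),
    sprintf("##$D1= %.10g", p$d1),
    sprintf("##$NUC1= <%s>", p$nuc$name),
    "##END="
  )
  writeLines(acqus, file.path(path, "acqus"))
  writeLines(c("##TITLE= indirect dimension",
               sprintf("##$TD= %d", length(ds$rows)),
               "##END="),
             file.path(path, "acqu2s"))
  meta <- list(schema = "slogp-meta/1",
               params = params_to_list(p),
               plan = plan_to_list(ds$plan),
               provenance = ds$provenance)
  jsonlite::write_json(meta, file.path(path, "slogp_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  path
}

parse_acqus <- function(file) {
  lines <- readLines(file, warn = FALSE)
  kv <- list()
  for (ln in grep("^##\\$", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^##\\$([A-Za-z0-9_]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  kv
}

acqus_num <- function(kv, key, file) {
  v <- kv[[key]]
  if (is.null(v))
    slogp_io_stop(sprintf("mandatory key '%s' missing from %s", key, file))
  as.numeric(v)
}

read_bruker <- function(path) {
  acqus_file <- file.path(path, "acqus")
  ser_file <- file.path(path, "ser")
  if (!file.exists(acqus_file)) slogp_io_stop(sprintf("no acqus file in %s", path))
  if (!file.exists(ser_file)) slogp_io_stop(sprintf("no ser file in %s", path))
  kv <- parse_acqus(acqus_file)
  td <- as.integer(acqus_num(kv, "TD", acqus_file))
  sw_h <- acqus_num(kv, "SW_h", acqus_file)
  bf1 <- acqus_num(kv, "BF1", acqus_file)
  o1 <- acqus_num(kv, "O1", acqus_file)
  ns <- as.integer(acqus_num(kv, "NS", acqus_file))
  ds_n <- as.integer(acqus_num(kv, "DS", acqus_file))
  d1 <- acqus_num(kv, "D1", acqus_file)
  bytorda <- as.integer(acqus_num(kv, "BYTORDA", acqus_file))
  dtypa <- as.integer(acqus_num(kv, "DTYPA", acqus_file))
  nc <- if (is.null(kv$NC)) 0L else as.integer(as.numeric(kv$NC))
  nuc_name <- gsub("[<>]", "", kv$NUC1 %||% "19F")

  n_rows <- 1L
  acqu2s_file <- file.path(path, "acqu2s")
  if (file.exists(acqu2s_file)) {
    kv2 <- parse_acqus(acqu2s_file)
    if (!is.null(kv2$TD)) n_rows <- as.integer(as.numeric(kv2$TD))
  }

  endian <- if (bytorda == 1L) "big" else "little"
  n_vals <- n_rows * td
  con <- file(ser_file, "rb")
  vals <- if (dtypa == 0L) {
    as.numeric(readBin(con, "integer", n = n_vals, size = 4L, endian = endian)) * 2^nc
  } else {
    readBin(con, "numeric", n = n_vals, size = 8L, endian = endian)
  }
  close(con)
  if (length(vals) != n_vals)
    slogp_io_stop(sprintf("ser holds %d values, expected %d", length(vals), n_vals))
  rows <- deinterleave(vals, n_rows, td)

  nuc <- nucleus(nuc_name)
  proton_freq <- bf1 / nuc$xi_ratio
  meta_file <- file.path(path, "slogp_meta.json")
  plan <- NULL
  prov <- NULL
  tau <- 0
  seed <- NA_integer_
  noise_sigma <- 0
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    plan <- list_to_plan(meta$plan)
    prov <- meta$provenance
    tau <- meta$params$tau %||% 0
    seed <- meta$params$seed %||% NA_integer_
    noise_sigma <- meta$params$noise_sigma %||% 0
  } else {
    warning("no slogp_meta.json sidecar: assuming row order (octanol, aqueous)")
    prov <- list(row_order = c("oct", "aq"))
  }
  params <- acq_params(proton_freq = proton_freq, o1p = o1 / bf1,
                       sweep_width = sw_h / bf1, td = td, ns = ns, ds = ds_n,
                       d1 = d1, tau = tau, noise_sigma = noise_sigma,
                       seed = if (is.na(seed)) 1L else seed, nuc = nuc)
  structure(list(rows = rows, params = params, plan = plan, provenance = prov),
            class = "pseudo_spectrum2d")
}

write_fixture <- function(ds, path) {
  if (!grepl("\\.slogp\\.json$", path))
    slogp_stop("fixture path must end in .slogp.json")
  bin_path <- sub("\\.json$", ".bin", path)
  vals <- interleave_rows(ds$rows)
  con <- file(bin_path, "wb")
  writeBin(vals, con, size = 8L, endian = "little")
  close(con)
  header <- list(
    schema = "slogp-fixture/1",
    acq = params_to_list(ds$params),
    plan = plan_to_list(ds$plan),
    provenance = ds$provenance,
    payload = list(file = basename(bin_path), dtype = "float64",
                   endian = "little", n_rows = length(ds$rows),
                   td = ds$params$td)
  )
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

read_fixture <- function(path) {
  if (!file.exists(path)) slogp_io_stop(sprintf("no such fixture: %s", path))
  header <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("schema", "acq", "plan", "provenance", "payload")
  extra <- setdiff(names(header), known)
  if (length(extra))
    warning(sprintf("ignoring unknown fixture fields: %s",
                    paste(extra, collapse = ", ")))
  if (is.null(header$schema) || !startsWith(header$schema, "slogp-fixture/"))
    slogp_io_stop("not a slogp fixture (missing/foreign schema field)")
  for (key in c("acq", "payload"))
    if (is.null(header[[key]]))
      slogp_io_stop(sprintf("mandatory key '%s' missing from %s", key, path))
  pay <- header$payload
  bin_path <- file.path(dirname(path), pay$file)
  if (!file.exists(bin_path)) slogp_io_stop(sprintf("payload missing: %s", bin_path))
  n_vals <- pay$n_rows * pay$td
  con <- file(bin_path, "rb")
  vals <- readBin(con, "numeric", n = n_vals, size = 8L,
                  endian = pay$endian %||% "little")
  close(con)
  if (length(vals) != n_vals)
    slogp_io_stop(sprintf("payload holds %d values, expected %d", length(vals), n_vals))
  structure(list(rows = deinterleave(vals, pay$n_rows, pay$td),
                 params = list_to_params(header$acq),
                 plan = list_to_plan(header$plan),
                 provenance = header$provenance),
            class = "pseudo_spectrum2d")
}

#' Read a pseudo-2D dataset, auto-detecting the dialect
#'
#' A directory is read as the Bruker-style dialect (`ser` + `acqus`);
#' a `*.slogp.json` file as the portable fixture format.
#'
#' @param path dataset directory or fixture header path.
#' @return a `pseudo_spectrum2d`.
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) return(read_bruker(path))
  if (grepl("\\.slogp\\.json$", path)) return(read_fixture(path))
  slogp_io_stop(sprintf(
    "cannot detect dataset dialect of '%s' (expected a directory or *.slogp.json)", path))
}

#' Write a log P result record
#'
#' Flat, documented schema shared by both formats: `analyte`,
#' `logp_true`, `i_oct`, `i_aq`, `snr_oct`, `snr_aq`, `mode`, `logp`,
#' `sigma_logp`, `logp_summed`, `logp_separate`, `seed`, `warnings`.
#' A missing uncertainty serializes as JSON `null` (CSV `NA`); warnings
#' collapse to one `|`-separated CSV field.
#'
#' @param result a `logp_result` from [run_pipeline()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!inherits(result, "logp_result")) slogp_stop("result must be a logp_result")
  flat <- list(analyte = result$analyte, logp_true = result$logp_true,
               i_oct = result$i_oct, i_aq = result$i_aq,
               snr_oct = result$snr_oct, snr_aq = result$snr_aq,
               mode = result$mode, logp = result$logp,
               sigma_logp = if (is.na(result$sigma_logp)) NULL else result$sigma_logp,
               logp_summed = result$logp_summed,
               logp_separate = result$logp_separate,
               seed = result$seed, warnings = as.list(result$warnings))
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    df <- data.frame(analyte = result$analyte, logp_true = result$logp_true,
                     i_oct = result$i_oct, i_aq = result$i_aq,
                     snr_oct = result$snr_oct, snr_aq = result$snr_aq,
                     mode = result$mode, logp = result$logp,
                     sigma_logp = result$sigma_logp,
                     logp_summed = result$logp_summed,
                     logp_separate = result$logp_separate,
                     seed = result$seed,
                     warnings = paste(result$warnings, collapse = "|"),
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
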