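# Shared readers/writers and the reproducible pipeline driver. All table
# columns carry unit suffixes in their headers (`_K`, `_mol_per_L`, `_mM`,
# `_nm_s`) to prevent silent unit bugs; `_mM` columns are converted to
# mol/L on read.

# schema: named character vector, name -> "numeric" | "character"
.schemas <- list(
  solubility = c(temperature_K = "numeric", solubility_mol_per_L = "numeric",
                 sd = "numeric"),
  vc = c(concentration_mM = "numeric", velocity_nm_s = "numeric",
         sd = "numeric"),
  trace = c(time_s = "numeric", displacement_nm = "numeric"),
  absorbance = c(concentration_mM = "numeric", absorbance = "numeric")
)

#' Read a typed CSV table against a named schema
#'
#' The header must contain every non-optional schema column (`sd` columns
#' are optional); unexpected columns are an error. Columns with an `_mM`
#' unit suffix are converted to mol/L and renamed `_mol_per_L`.
#'
#' @param path CSV path
#' @param schema one of `"solubility"`, `"vc"`, `"trace"`, `"absorbance"`
#' @return data.frame with typed, unit-suffixed columns
#' @export
read_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  sch <- .schemas[[schema]]
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(names(sch), "sd")
  missing_cols <- setdiff(required, names(df))
  extra <- setdiff(names(df), names(sch))
  if (length(missing_cols) > 0 || length(extra) > 0) {
    stop(sprintf("schema error in %s: expected columns {%s}; found {%s}",
                 path, paste(names(sch), collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  for (nm in names(df)) {
    df[[nm]] <- if (sch[[nm]] == "numeric") as.numeric(df[[nm]]) else
      as.character(df[[nm]])
  }
  mM <- grep("_mM$", names(df))
  for (j in mM) {
    df[[j]] <- df[[j]] * 1e-3
    names(df)[j] <- sub("_mM$", "_mol_per_L", names(df)[j])
  }
  df
}

#' Write a data.frame as CSV (round-trip partner of [read_table()])
#'
#' @param df data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a height map in the plain-text grid dialect
#'
#' Header lines `# rows= cols= pixel_size_nm= time_s=` followed by
#' whitespace-delimited heights in nm, one image row per line.
#'
#' @param frame numeric matrix, heights in nm
#' @param path output path
#' @param pixel_size_nm pixel size, nm
#' @param time_s frame timestamp, s
#' @return `path`, invisibly
#' @export
write_heightmap <- function(frame, path, pixel_size_nm, time_s = 0) {
  stopifnot(is.matrix(frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rows=%d cols=%d pixel_size_nm=%.10g time_s=%.10g",
                     nrow(frame), ncol(frame), pixel_size_nm, time_s), con)
  writeLines(apply(frame, 1, function(r) paste(format(r, digits = 17),
                                               collapse = " ")), con)
  invisible(path)
}

#' Read a height map written by [write_heightmap()]
#'
#' @param path input path
#' @return numeric matrix with attributes `pixel_size_nm` and `time_s`
#' @export
read_heightmap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  if (!startsWith(hdr, "#")) stop("missing heightmap header line", call. = FALSE)
  get_field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9eE+.-]+"), hdr))
    if (length(m) == 0) stop("heightmap header missing field: ", key,
                             call. = FALSE)
    as.numeric(sub(paste0(key, "="), "", m))
  }
  nr <- as.integer(get_field("rows"))
  nc <- as.integer(get_field("cols"))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    stop(sprintf("heightmap parse error: expected %d rows, found %d",
                 nr, length(body)), call. = FALSE)
  }
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  widths <- lengths(rows)
  if (any(widths != nc)) {
    stop(sprintf("heightmap parse error: ragged row (expected %d values, found %d)",
                 nc, widths[which(widths != nc)[1]]), call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "pixel_size_nm") <- get_field("pixel_size_nm")
  attr(out, "time_s") <- get_field("time_s")
  out
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes an ordered list of stages over a shared state, failing fast with
#' stage-attributed errors, and returns an append-only manifest recording
#' per-stage seeds, outputs and timing. Built-in stages:
#' \describe{
#'   \item{synth_vc}{generate a v(C) dataset ([gen_vc()])}
#'   \item{kinetics}{fit linear/power/quadratic laws and select a model}
#'   \item{synth_solubility}{generate Ce(T) data ([gen_solubility()])}
#'   \item{thermo}{van 't Hoff fit}
#' }
#' A stage entry is `list(stage = "<name>", ...params)`. An empty stage list
#' yields an empty manifest.
#'
#' @param stages list of stage entries
#' @param seed base seed; stage i uses `seed + i` unless the stage carries
#'   its own
#' @param verbose print stage log lines (verbosity never changes results)
#' @return list with `state` (stage outputs by name) and `manifest`
#'   (data.frame: stage, seed, elapsed_s, status)
#' @export
run_pipeline <- function(stages = list(), seed = 1L, verbose = FALSE) {
  state <- list()
  manifest <- data.frame(stage = character(0), seed = integer(0),
                         elapsed_s = numeric(0), status = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    entry <- stages[[i]]
    nm <- entry$stage
    if (is.null(nm)) stop("pipeline stage ", i, " has no `stage` name",
                          call. = FALSE)
    st_seed <- if (!is.null(entry$seed)) entry$seed else seed + i
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      switch(nm,
        synth_vc = {
          args <- entry[setdiff(names(entry), c("stage", "seed"))]
          state$vc <- do.call(gen_vc, c(args, list(seed = st_seed)))
        },
        kinetics = {
          if (is.null(state$vc)) stop("no v(C) dataset in pipeline state")
          fits <- list(fit_linear_bcf(state$vc), fit_power_law(state$vc),
                       fit_kink_limited(state$vc))
          state$kinetics <- list(fits = fits, ranking = select_model(fits))
        },
        synth_solubility = {
          args <- entry[setdiff(names(entry), c("stage", "seed"))]
          state$solubility <- do.call(gen_solubility,
                                      c(args, list(seed = st_seed)))
        },
        thermo = {
          if (is.null(state$solubility)) stop("no solubility data in pipeline state")
          state$thermo <- fit_vant_hoff(state$solubility)
        },
        stop("unknown pipeline stage: ", nm)
      )
      "ok"
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' (position %d) failed: %s",
                   nm, i, conditionMessage(e)), call. = FALSE)
    })
    el <- proc.time()[["elapsed"]] - t0
    if (verbose) {
      message(sprintf("[%s] stage=%s seed=%d elapsed=%.3fs",
                      format(Sys.time(), "%H:%M:%S"), nm, st_seed, el))
    }
    manifest <- rbind(manifest,
                      data.frame(stage = nm, seed = st_seed, elapsed_s = el,
                                 status = res, stringsAsFactors = FALSE))
  }
  list(state = state, manifest = manifest)
}

#' Write a JSON run report
#'
#' @param x a list (estimates, standard errors, residuals, ...)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
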