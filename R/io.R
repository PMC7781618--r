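# Recording serialization. Two dialects:
#  * a tab-separated sweep matrix with a "# key = value" metadata header
#    (Axon-Text-File style; the interchange format), and
#  * an RDS container holding the recording object verbatim (binary dialect,
#    written/read at run time).
# Native ABF parsing is out of scope; export recordings to the text dialect.

.trace_magic <- "# cavgating-trace v1"

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6f", x))
}

encode_segments <- function(segments) {
  paste(sprintf("%g:%g", segments$v, segments$dur), collapse = ";")
}

decode_segments <- function(txt) {
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  sweep_segments(v = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
                 dur = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

#' Write a recording
#'
#' @param rec A `vc_recording`.
#' @param path Output file.
#' @param format `"text"` for the tab-separated sweep-matrix dialect
#'   (lossless to 1e-6 pA, write-read-write idempotent) or `"rds"` for the
#'   structured binary container.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("text", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "vc_recording"))
  if (format == "rds") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  # flatten: main/leakref sweeps first, then P/4 subsweeps with parent refs
  traces <- list()
  meta_sweeps <- character()
  add <- function(current, line) {
    traces[[length(traces) + 1L]] <<- current
    meta_sweeps[length(meta_sweeps) + 1L] <<- line
  }
  for (i in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[i]]
    add(sw$current, sprintf(
      "# sweep %d role=%s test_v=%s cond_v=%s step_segment=%s control_segment=%s test_segment=%s parent=NA segments=%s",
      i, sw$role,
      sw$test_v %||% "NA", sw$cond_v %||% "NA",
      sw$step_segment %||% "NA", sw$control_segment %||% "NA",
      sw$test_segment %||% "NA", encode_segments(sw$segments)))
  }
  for (i in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[i]]
    if (!is.null(sw$p4_currents)) {
      for (k in seq_along(sw$p4_currents)) {
        add(sw$p4_currents[[k]], sprintf(
          "# sweep %d.%d role=p4sub test_v=%s cond_v=NA step_segment=NA control_segment=NA test_segment=NA parent=%d segments=%s",
          i, k, sw$test_v %||% "NA", i, encode_segments(sw$p4_segments)))
      }
    }
  }
  p <- rec$protocol
  head <- c(
    .trace_magic,
    sprintf("# construct = %s", rec$construct),
    sprintf("# cell_id = %s", rec$cell_id),
    sprintf("# dt_ms = %g", rec$dt),
    sprintf("# c_m_pf = %g", rec$c_m),
    sprintf("# seed = %s", rec$seed %||% "NA"),
    sprintf("# leak_method = %s", rec$leak_method),
    sprintf("# leak_subtracted = %s", rec$leak_subtracted),
    sprintf("# protocol_kind = %s", p$kind),
    sprintf("# holding_potential = %g", p$holding_potential),
    sprintf("# step_increment = %g", p$step_increment),
    sprintf("# step_duration = %g", p$step_duration),
    sprintf("# voltage_range = %g;%g", p$voltage_range[1], p$voltage_range[2]),
    sprintf("# conditioning_duration = %g", p$conditioning_duration),
    sprintf("# intersweep_interval = %g", p$intersweep_interval),
    sprintf("# pre_ms = %g", p$pre_ms),
    sprintf("# post_ms = %g", p$post_ms),
    sprintf("# gap_ms = %g", p$gap_ms),
    meta_sweeps
  )
  n_max <- max(vapply(traces, length, integer(1)))
  mat <- vapply(traces, function(tr) {
    c(fmt_num(tr), rep("NA", n_max - length(tr)))
  }, character(n_max))
  time_col <- sprintf("%.4f", seq_len(n_max) * rec$dt)
  header <- paste(c("time_ms", sprintf("sweep_%03d", seq_along(traces))),
                  collapse = "\t")
  body <- paste(time_col, apply(mat, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(head, header, body), path)
  invisible(path)
}

meta_value <- function(meta, key, required = TRUE) {
  hit <- grep(paste0("^# ", key, " = "), meta, value = TRUE)
  if (length(hit) == 0L) {
    if (required) stop("trace file is missing metadata key: ", key)
    return(NA_character_)
  }
  sub(paste0("^# ", key, " = "), "", hit[1])
}

kv_field <- function(line, key) {
  m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

num_or_null <- function(x) {
  if (is.na(x) || x == "NA") NULL else as.numeric(x)
}

#' Read a recording
#'
#' @param path File written by [write_recording()].
#' @param format `"text"` or `"rds"`.
#' @return A `vc_recording`.
#' @export
read_recording <- function(path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    rec <- readRDS(path)
    stopifnot(inherits(rec, "vc_recording"))
    return(rec)
  }
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != .trace_magic) {
    stop("not a cavgating trace file (missing '", .trace_magic, "' header)")
  }
  meta_end <- which(!startsWith(lines, "#"))[1]
  if (is.na(meta_end)) stop("malformed trace file: no data section")
  meta <- lines[seq_len(meta_end - 1L)]
  dt <- as.numeric(meta_value(meta, "dt_ms"))
  if (!is.finite(dt) || dt <= 0) stop("invalid dt_ms metadata")

  header <- strsplit(lines[meta_end], "\t", fixed = TRUE)[[1]]
  n_col <- length(header)
  body <- strsplit(lines[-seq_len(meta_end)], "\t", fixed = TRUE)
  bad <- which(lengths(body) != n_col)
  if (length(bad)) {
    stop("inconsistent column count at data row ", bad[1],
         " (expected ", n_col, ", got ", lengths(body)[bad[1]], ")")
  }
  vals <- matrix(suppressWarnings(as.numeric(unlist(body))),
                 ncol = n_col, byrow = TRUE)
  cur_mat <- vals[, -1L, drop = FALSE]

  sweep_meta <- grep("^# sweep ", meta, value = TRUE)
  if (length(sweep_meta) != ncol(cur_mat)) {
    stop("sweep metadata lines (", length(sweep_meta),
         ") do not match sweep columns (", ncol(cur_mat), ")")
  }
  parsed <- lapply(seq_along(sweep_meta), function(j) {
    line <- sweep_meta[j]
    segments <- decode_segments(kv_field(line, "segments"))
    n <- sum(segment_samples(segments, dt))
    cur <- cur_mat[seq_len(n), j]
    if (anyNA(cur)) stop("sweep ", j, " is shorter than its segment table")
    list(role = kv_field(line, "role"),
         test_v = num_or_null(kv_field(line, "test_v")),
         cond_v = num_or_null(kv_field(line, "cond_v")),
         step_segment = {
           x <- num_or_null(kv_field(line, "step_segment"))
           if (is.null(x)) NULL else as.integer(x)
         },
         control_segment = {
           x <- num_or_null(kv_field(line, "control_segment"))
           if (is.null(x)) NULL else as.integer(x)
         },
         test_segment = {
           x <- num_or_null(kv_field(line, "test_segment"))
           if (is.null(x)) NULL else as.integer(x)
         },
         parent = num_or_null(kv_field(line, "parent")),
         segments = segments, current = cur)
  })
  sweeps <- Filter(function(s) is.null(s$parent), parsed)
  for (s in Filter(function(s) !is.null(s$parent), parsed)) {
    k <- s$parent
    sweeps[[k]]$p4_segments <- s$segments
    sweeps[[k]]$p4_currents <- c(sweeps[[k]]$p4_currents, list(s$current))
  }
  sweeps <- lapply(sweeps, function(s) {
    s$parent <- NULL
    s
  })

  vr <- as.numeric(strsplit(meta_value(meta, "voltage_range"), ";")[[1]])
  cond <- suppressWarnings(as.numeric(meta_value(meta, "conditioning_duration")))
  proto <- voltage_protocol(
    kind = meta_value(meta, "protocol_kind"),
    holding_potential = as.numeric(meta_value(meta, "holding_potential")),
    step_increment = as.numeric(meta_value(meta, "step_increment")),
    step_duration = as.numeric(meta_value(meta, "step_duration")),
    voltage_range = vr,
    conditioning_duration = cond,
    intersweep_interval = as.numeric(meta_value(meta, "intersweep_interval")),
    dt = dt,
    pre_ms = as.numeric(meta_value(meta, "pre_ms")),
    post_ms = as.numeric(meta_value(meta, "post_ms")),
    gap_ms = as.numeric(meta_value(meta, "gap_ms")))
  seed_txt <- meta_value(meta, "seed")
  rec <- new_recording(
    sweeps, dt, as.numeric(meta_value(meta, "c_m_pf")), proto,
    meta_value(meta, "cell_id"), meta_value(meta, "construct"),
    if (seed_txt == "NA") NULL else as.integer(seed_txt),
    leak_method = meta_value(meta, "leak_method"))
  rec$leak_subtracted <- identical(meta_value(meta, "leak_subtracted"), "TRUE")
  rec
}

# ---- run configuration ------------------------------------------------------

.config_keys <- list(
  top = c("seed", "output_dir", "protocols", "preprocess", "cohorts",
          "comparisons", "reference"),
  protocols = c("use", "iv_step_duration", "dt"),
  preprocess = c("ljp", "leak", "peak_window_start_ms", "smooth_ms"),
  cohort = c("construct", "n_cells", "seed", "g_max", "noise_sd", "g_leak",
             "g_max_sigma", "c_m_sd", "tau_fast", "tau_slow", "frac_fast",
             "qc_outlier_frac")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
  }
}

#' Read and validate a pipeline run configuration
#'
#' The YAML configuration declares which construct cohorts to simulate
#' (rows of [reference_gating()] with optional overrides), which protocols
#' to run, preprocessing options and the statistical comparison set.
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A validated `run_config` list with defaults filled in and the
#'   file's MD5 hash in `$config_hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, .config_keys$top, "top level")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "cavgating-out"
  cfg$comparisons <- match.arg(cfg$comparisons %||% "reference",
                               c("reference", "allpairs"))
  cfg$protocols <- cfg$protocols %||% list()
  check_keys(cfg$protocols, .config_keys$protocols, "protocols")
  cfg$protocols$use <- cfg$protocols$use %||% c("iv", "ssi", "inact5s")
  stopifnot(all(cfg$protocols$use %in% c("iv", "ssi", "inact5s")))
  cfg$protocols$iv_step_duration <- cfg$protocols$iv_step_duration %||% 20
  cfg$protocols$dt <- cfg$protocols$dt %||% 0.05
  cfg$preprocess <- cfg$preprocess %||% list()
  check_keys(cfg$preprocess, .config_keys$preprocess, "preprocess")
  cfg$preprocess$ljp <- cfg$preprocess$ljp %||% 0
  cfg$preprocess$leak <- match.arg(cfg$preprocess$leak %||% "offline",
                                   c("offline", "p4", "none"))
  if (is.null(cfg$cohorts) || length(cfg$cohorts) == 0L) {
    stop("config must declare at least one cohort")
  }
  known <- reference_gating()$construct
  for (i in seq_along(cfg$cohorts)) {
    check_keys(cfg$cohorts[[i]], .config_keys$cohort,
               paste0("cohorts[", i, "]"))
    if (is.null(cfg$cohorts[[i]]$construct)) {
      stop("cohorts[", i, "] is missing `construct`")
    }
    if (!cfg$cohorts[[i]]$construct %in% known) {
      stop("cohorts[", i, "]: unknown construct '",
           cfg$cohorts[[i]]$construct, "'")
    }
  }
  cfg$reference <- cfg$reference %||% cfg$cohorts[[1]]$construct
  cfg$config_hash <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}
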