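#' Read and write spike sessions
#'
#' Two on-disk dialects are supported. `"table"` is a directory holding a
#' flat per-spike CSV (`spikes.csv`: session_id, neuron_id, trial_index,
#' condition, outcome, spike_time_ms), a trial-metadata CSV (`trials.csv`:
#' trial_index, condition, outcome, eot_time_ms) and a small `meta.json`
#' (session_id, performance, epoch). `"container"` is a single hierarchical
#' JSON file with the layout `trials` (table), `spikes/<neuron_id>/<trial>`
#' (integer millisecond arrays) and `meta` (session_id, performance, epoch),
#' convenient for large sessions. Timestamps live on a 1 ms integer grid in
#' both dialects, so `read_session(write_session(s))` reproduces `s`
#' bit-exactly.
#'
#' Unknown extra columns in the flat tables are ignored with a warning;
#' missing mandatory columns, unknown condition/outcome labels and
#' non-monotone timestamps are errors.
#'
#' @param path Directory (`"table"`) or file (`"container"`) path.
#' @param format `"table"` or `"container"`.
#' @param session A `spike_session`.
#' @return `read_session` returns a `spike_session`; `write_session`
#'   returns `path` invisibly.
#' @seealso [spike_session()], [read_deposited_fixture()]
#' @export
read_session <- function(path, format = c("table", "container")) {
  format <- match.arg(format)
  if (format == "table") read_session_table(path) else read_session_json(path)
}

#' @rdname read_session
#' @export
write_session <- function(session, path, format = c("table", "container")) {
  format <- match.arg(format)
  validate_spike_session(session)
  if (format == "table") write_session_table(session, path)
  else write_session_json(session, path)
  invisible(path)
}

read_session_table <- function(path) {
  if (!dir.exists(path)) {
    abort(paste0("no session directory at ", path), class = "neff_io_error")
  }
  spikes_f <- file.path(path, "spikes.csv")
  trials_f <- file.path(path, "trials.csv")
  meta_f <- file.path(path, "meta.json")
  for (f in c(spikes_f, trials_f, meta_f)) {
    if (!file.exists(f)) {
      abort(paste0("missing file: ", f), class = "neff_format_error")
    }
  }
  spikes <- readr::read_csv(spikes_f, show_col_types = FALSE,
                            progress = FALSE)
  trials <- readr::read_csv(trials_f, show_col_types = FALSE,
                            progress = FALSE)
  need_sp <- c("session_id", "neuron_id", "trial_index", "condition",
               "outcome", "spike_time_ms")
  need_tr <- c("trial_index", "condition", "outcome")
  miss <- setdiff(need_sp, names(spikes))
  if (length(miss)) {
    abort(paste0("spikes.csv lacks mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "neff_format_error")
  }
  miss <- setdiff(need_tr, names(trials))
  if (length(miss)) {
    abort(paste0("trials.csv lacks mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "neff_format_error")
  }
  extra <- setdiff(names(spikes), need_sp)
  if (length(extra)) {
    warn(paste0("ignoring unknown spike-table column(s): ",
                paste(extra, collapse = ", ")))
  }
  extra <- setdiff(names(trials), c(need_tr, "eot_time_ms"))
  if (length(extra)) {
    warn(paste0("ignoring unknown trial-table column(s): ",
                paste(extra, collapse = ", ")))
  }
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  spike_session(
    session_id = meta$session_id,
    trials = trials[, intersect(c(need_tr, "eot_time_ms"), names(trials))],
    spikes = tibble(neuron_id = as.character(spikes$neuron_id),
                    trial_index = as.integer(spikes$trial_index),
                    time_ms = as.integer(spikes$spike_time_ms)),
    performance = meta$performance,
    epoch = as.numeric(meta$epoch))
}

write_session_table <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- session$spikes |>
    left_join(session$trials[, c("trial_index", "condition", "outcome")],
              by = "trial_index") |>
    mutate(session_id = session$session_id) |>
    select("session_id", "neuron_id", "trial_index", "condition",
           "outcome", spike_time_ms = "time_ms")
  readr::write_csv(sp, file.path(path, "spikes.csv"), progress = FALSE)
  readr::write_csv(session$trials, file.path(path, "trials.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(session_id = session$session_id,
         performance = session$performance,
         epoch = session$epoch),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
}

write_session_json <- function(session, path) {
  sp <- split(session$spikes, session$spikes$neuron_id)
  spikes <- lapply(sp, function(d) {
    lapply(split(d$time_ms, d$trial_index), as.integer)
  })
  obj <- list(
    meta = list(session_id = session$session_id,
                performance = session$performance,
                epoch = session$epoch),
    trials = session$trials,
    spikes = spikes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

read_session_json <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "neff_io_error")
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(paste0("not a session container: ", path),
                          class = "neff_format_error")
                  })
  for (fld in c("meta", "trials")) {
    if (is.null(obj[[fld]])) {
      abort(paste0("container lacks the '", fld, "' group"),
            class = "neff_format_error")
    }
  }
  spikes <- tibble(neuron_id = character(), trial_index = integer(),
                   time_ms = integer())
  if (length(obj$spikes)) {
    spikes <- imap(obj$spikes, function(trials, nid) {
      imap(trials, function(ts, tr) {
        tibble(neuron_id = nid, trial_index = as.integer(tr),
               time_ms = as.integer(ts))
      }) |> list_rbind()
    }) |> list_rbind()
  }
  spike_session(session_id = obj$meta$session_id,
                trials = obj$trials,
                spikes = arrange(spikes, .data$neuron_id,
                                 .data$trial_index, .data$time_ms),
                performance = obj$meta$performance,
                epoch = as.numeric(obj$meta$epoch))
}

#' Read a deposited summary fixture (PSTH + binary states)
#'
#' Parses the two-structure summary layout that accompanies the raw
#' recordings: a `PSTH` structure holding per-neuron average firing rates in
#' 25 ms non-overlapping bins from -0.5 s to 1.5 s around tone onset, split
#' into GO and NOGO trial groups, and a `BinaryData` structure holding each
#' neuron's binary state per trial. The on-disk realisation here is a JSON
#' container with those two top-level structures (see
#' [generate_fixture_file()] for the writer); unknown extra fields inside
#' either structure are tolerated and ignored.
#'
#' @param path Path to the fixture file.
#' @return A list with `psth` — a tibble (neuron_id, condition, bin_start_s,
#'   rate_hz) covering 80 bins per condition — and `binary` — a tibble
#'   (neuron_id, trial_index, condition, state).
#' @export
read_deposited_fixture <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(paste0("empty or missing fixture file: ", path),
          class = "neff_format_error")
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(paste0("unparseable fixture file: ", path),
                          class = "neff_format_error")
                  })
  for (fld in c("PSTH", "BinaryData")) {
    if (is.null(obj[[fld]])) {
      abort(paste0("fixture lacks the '", fld, "' structure"),
            class = "neff_format_error")
    }
  }
  ps <- obj$PSTH
  bin_w <- as.numeric(ps$bin_width_s)
  edges <- as.numeric(ps$bin_start_s)
  n_bins <- round((1.5 - (-0.5)) / bin_w)
  if (length(edges) != n_bins ||
      abs(edges[1] - (-0.5)) > 1e-9 ||
      abs(edges[length(edges)] + bin_w - 1.5) > 1e-9) {
    abort("PSTH bins inconsistent with the -0.5..1.5 s / 25 ms grid",
          class = "neff_validation_error")
  }
  psth <- map(c("GO", "NOGO"), function(cond) {
    m <- ps$rates_hz[[cond]]
    if (is.null(m)) {
      abort(paste0("PSTH structure lacks the ", cond, " group"),
            class = "neff_format_error")
    }
    m <- as.matrix(m)
    tibble(neuron_id = rep(as.character(ps$neuron_id), times = ncol(m)),
           condition = cond,
           bin_start_s = rep(edges, each = nrow(m)),
           rate_hz = as.vector(m))
  }) |> list_rbind()
  bd <- obj$BinaryData
  states <- as.matrix(bd$states)
  binary <- tibble(
    neuron_id = rep(as.character(bd$neuron_id), times = ncol(states)),
    trial_index = rep(as.integer(bd$trial_index), each = nrow(states)),
    condition = rep(as.character(bd$condition), each = nrow(states)),
    state = as.integer(as.vector(states)))
  list(psth = psth, binary = binary)
}
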