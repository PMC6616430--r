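SECTORING_STAGES <- c("columns", "split8", "post_latch_16", "completion")

#' Load a sectoring event file
#'
#' Events are data, not code: each record names a stage, a target cell
#' set (column base at anticodon position 2; row bases at position 3,
#' comma-separated or `*`; wobble half `A`, `B` or `*`; optionally an
#' explicit codon list restricting the event to single codons of a
#' cell), the incoming amino acid and the amino acid it displaces.
#' The packaged file encodes the stepwise working model of code
#' sectoring; edited copies can be supplied to simulate alternative
#' orderings.
#'
#' @param path Path to a tab-separated event file; default is the
#'   packaged file.
#' @return Data frame of events with a `stage` factor ordered
#'   `columns`, `split8`, `post_latch_16`, `completion`.
#' @export
sectoring_events <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sectoring_events.tsv",
                        package = "trnacode", mustWork = TRUE)
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("stage", "column", "rows", "half", "codons", "incoming",
            "displaced", "rule")
  if (!all(need %in% names(ev)))
    stop("event file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(ev$stage %in% SECTORING_STAGES))
    stop("unknown stage label in event file", call. = FALSE)
  if (any(ev$incoming == ev$displaced))
    stop("an event may not displace its own amino acid", call. = FALSE)
  ev
}

#' The all-glycine initial code state
#'
#' At the posited early stage every anticodon encoded Gly and any
#' mRNA sequence templated polyglycine.
#'
#' @return A `code_state` with all 64 codons assigned Gly and stage
#'   label `"initial"`.
#' @export
initial_state <- function() {
  new_code_state(setNames(rep("Gly", 64L), names(STANDARD_CODE)), "initial")
}

# Codons targeted by one event record.
event_codons <- function(state, event) {
  sel <- state$column == event$column
  if (event$rows != "*")
    sel <- sel & state$row %in% strsplit(event$rows, ",", fixed = TRUE)[[1]]
  if (event$half != "*") sel <- sel & state$half == event$half
  codons <- state$codon[sel]
  if (nzchar(event$codons)) {
    explicit <- strsplit(event$codons, ",", fixed = TRUE)[[1]]
    if (!all(explicit %in% codons))
      stop("event codon list ", event$codons,
           " is not inside the targeted cell set", call. = FALSE)
    codons <- explicit
  }
  if (length(codons) == 0L)
    stop("event targets no codons: ", event$incoming, " <- ",
         event$displaced, call. = FALSE)
  codons
}

apply_event <- function(state, event) {
  codons <- event_codons(state, event)
  current <- unique(state$assignment[state$codon %in% codons])
  if (!identical(current, event$displaced))
    stop("event expects ", event$displaced, " at ",
         paste(codons, collapse = ","), " but found ",
         paste(current, collapse = "/"), call. = FALSE)
  state$assignment[state$codon %in% codons] <- event$incoming
  state
}

#' Apply one sectoring stage
#'
#' Applies every event of the named stage, enforcing stage order (the
#' incoming state must carry the immediately preceding stage label)
#' and checking that each event displaces the amino acid it declares.
#'
#' @param state A `code_state`.
#' @param stage One of `"columns"`, `"split8"`, `"post_latch_16"`,
#'   `"completion"`.
#' @param events Event table from [sectoring_events()].
#' @return The updated `code_state`, stage label advanced.
#' @export
apply_stage <- function(state, stage, events = sectoring_events()) {
  stopifnot(inherits(state, "code_state"))
  stage <- match.arg(stage, SECTORING_STAGES)
  want_prev <- c("initial", head(SECTORING_STAGES, -1L))[
    match(stage, SECTORING_STAGES)]
  if (!identical(attr(state, "stage"), want_prev))
    stop("stage '", stage, "' must be applied to a '", want_prev,
         "' state, not '", attr(state, "stage"), "'", call. = FALSE)
  for (i in which(events$stage == stage))
    state <- apply_event(state, events[i, ])
  attr(state, "stage") <- stage
  state
}

#' @rdname apply_stage
#' @export
stage_columns <- function(state, events = sectoring_events())
  apply_stage(state, "columns", events)

#' @rdname apply_stage
#' @export
stage_split8 <- function(state, events = sectoring_events())
  apply_stage(state, "split8", events)

#' @rdname apply_stage
#' @export
stage_post_latch <- function(state, events = sectoring_events())
  apply_stage(state, "post_latch_16", events)

#' @rdname apply_stage
#' @export
stage_completion <- function(state, events = sectoring_events())
  apply_stage(state, "completion", events)

#' Run the full sectoring trajectory
#'
#' From the all-Gly state, applies the four stages in order: column
#' sectoring at anticodon position 2 (Val/Ala/Asp/Gly); the ~8-letter
#' split (purine rows of columns 1, 2 and 4 ceded to Leu/Pro/Arg,
#' column 3 split at the wobble half into Asp/Glu); the post-latch
#' row-resolved additions (Ile, Thr, Ser, Asn, His, Lys, Gln); and
#' completion (Met, Phe, Tyr, Cys, Trp, the Ser and Arg gains in
#' column 4, and the stops).
#'
#' @param events Event table from [sectoring_events()].
#' @return An object of class `sectoring_trajectory`: list with
#'   `initial` (the all-Gly state), `stages` (per stage: label, event
#'   rows, resulting state) and `final` (the last state).
#' @export
run_full_trajectory <- function(events = sectoring_events()) {
  state <- initial_state()
  stages <- list()
  for (st in SECTORING_STAGES) {
    state <- apply_stage(state, st, events)
    stages[[st]] <- list(stage = st,
                         events = events[events$stage == st, ],
                         state = state)
  }
  structure(list(initial = initial_state(), stages = stages,
                 final = state, events = events),
            class = "sectoring_trajectory")
}

#' @export
print.sectoring_trajectory <- function(x, ...) {
  cat("Sectoring trajectory:", length(x$stages), "stages\n")
  for (s in x$stages)
    cat(sprintf("  %-14s %2d events -> %2d amino acids%s\n", s$stage,
                nrow(s$events), length(amino_acids(s$state)),
                if ("STOP" %in% s$state$assignment) " + STOP" else ""))
  invisible(x)
}

#' Audit displacements against the anticodon preference scale
#'
#' For every (column, displaced amino acid) pair in the trajectory,
#' compares the position-3 ordinals (C = 2, U = G = 1, A = 0) of the
#' cells the incumbent ceded to later amino acids with the cells it
#' still holds in the final state.  The working model predicts that
#' incumbents invariably retain their most favored cells, i.e. the
#' minimum retained ordinal is at least the maximum ceded ordinal.
#' Cells ceded to STOP are exempt: stops are read by proteins, not
#' tRNAs, and are outside the anticodon preference rules.  Incumbents
#' that ceded an entire column retain nothing there and are skipped as
#' vacuous.
#'
#' @param trajectory A completed [run_full_trajectory()] result.
#' @return Data frame of class `displacement_audit` with one row per
#'   (column, displaced) pair: ceded cells and their maximum ordinal,
#'   retained cells and their minimum ordinal, and a `violation` flag.
#' @export
displacement_audit <- function(trajectory) {
  stopifnot(inherits(trajectory, "sectoring_trajectory"))
  events <- trajectory$events
  final <- trajectory$final

  # Replay to know the cell set each event removed from its incumbent.
  state <- initial_state()
  ceded <- list()  # key column|displaced -> character cells
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    codons <- event_codons(state, ev)
    if (ev$incoming != "STOP" && ev$displaced != "STOP") {
      key <- paste(ev$column, ev$displaced, sep = "|")
      cells <- unique(state$cell[state$codon %in% codons])
      ceded[[key]] <- union(ceded[[key]], cells)
    }
    state <- apply_event(state, ev)
  }

  rows <- lapply(names(ceded), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    column <- parts[1]; aa <- parts[2]
    ceded_cells <- sort(ceded[[key]])
    retained_cells <- sort(unique(
      final$cell[final$column == column & final$assignment == aa]))
    ord_of <- function(cells)
      PREFERENCE_ORDINAL[final$row[match(cells, final$cell)]]
    data.frame(
      column = column, displaced = aa,
      ceded = paste(ceded_cells, collapse = ","),
      ceded_max_ordinal = max(ord_of(ceded_cells)),
      retained = paste(retained_cells, collapse = ","),
      retained_min_ordinal = if (length(retained_cells))
        min(ord_of(retained_cells)) else NA_integer_,
      violation = length(retained_cells) > 0L &&
        min(ord_of(retained_cells)) < max(ord_of(ceded_cells)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("displacement_audit", class(out))
  out
}

#' Write a trajectory to disk
#'
#' One per-stage CSV code table plus a JSON event log.
#'
#' @param trajectory A `sectoring_trajectory`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "sectoring_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in trajectory$stages) {
    p <- file.path(dir, paste0("state_", s$stage, ".csv"))
    write_code_state_csv(s$state, p)
    paths <- c(paths, p)
  }
  log_path <- file.path(dir, "events.json")
  jsonlite::write_json(trajectory$events, log_path, dataframe = "rows",
                       pretty = TRUE)
  invisible(c(paths, log_path))
}
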