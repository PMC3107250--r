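# File output: XYZ snapshots for molecular viewers, delimited track/event/
# FPT tables with header comments, and a resolved-config echo so every
# output directory is self-describing and reproducible.

.xyz_element <- c(pom_anchor = "H", scaffold = "C", fg_central = "N",
                  fg_peripheral = "O", cargo = "S")

#' Write a coordinates-only XYZ snapshot
#'
#' Bead groups map to element symbols (anchors H, scaffold C, central FG N,
#' peripheral FG O, cargo S); the simulation plane is written as z = 0.
#'
#' @param structure an `npc_structure`.
#' @param path output file.
#' @param positions optional N x 2 matrix overriding stored coordinates.
#' @param comment second-line comment string.
#' @return the path, invisibly.
#' @export
write_xyz <- function(structure, path, positions = NULL,
                      comment = "npcbd snapshot") {
  b <- structure$beads
  if (!is.null(positions)) {
    b$x <- positions[seq_len(nrow(b)), 1]
    b$y <- positions[seq_len(nrow(b)), 2]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", nrow(b)), comment), con)
  writeLines(sprintf("%s %.6f %.6f 0.000000",
                     .xyz_element[b$group], b$x, b$y), con)
  invisible(path)
}

#' Write the structure as tabular bead/bond/chain listings
#'
#' @param structure an `npc_structure`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_structure <- function(structure, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(structure$beads, file.path(dir, "beads.tsv"))
  .write_tsv(structure$bonds, file.path(dir, "bonds.tsv"))
  .write_tsv(structure$wlc, file.path(dir, "wlc_segments.tsv"))
  chains <- structure$chains
  if (nrow(chains) > 0) {
    chains$bead_ids <- vapply(chains$bead_ids, paste, character(1),
                              collapse = ",")
  }
  .write_tsv(chains, file.path(dir, "chains.tsv"))
  write_xyz(structure, file.path(dir, "structure.xyz"))
  invisible(dir)
}

.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a transport record's track and episodes
#'
#' @param record a `transport_record`.
#' @param prefix file path prefix (the function appends `_track.tsv` and
#'   `_episodes.tsv`).
#' @return written file paths, invisibly.
#' @export
write_track <- function(record, prefix) {
  stopifnot(inherits(record, "transport_record"))
  hdr <- sprintf("dt=%g (0.1 ns units) seed=%g outcome=%s", record$dt,
                 record$seed, record$events$outcome)
  p1 <- .write_tsv(record$track, paste0(prefix, "_track.tsv"), hdr)
  p2 <- .write_tsv(record$episodes, paste0(prefix, "_episodes.tsv"), hdr)
  invisible(c(p1, p2))
}

#' Write all outputs of a batch
#'
#' Per-run track/episode tables, the aggregate outcome and first-passage
#' tables, and the resolved configuration with the seeds used - enough to
#' reproduce the batch exactly. File contents are deterministic given
#' identical inputs.
#'
#' @param batch result of [run_batch()].
#' @param dir destination directory.
#' @param config optional `run_config` to echo.
#' @return the directory, invisibly.
#' @export
write_outputs <- function(batch, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create output directory %s", dir),
          class = "npcbd_io_error")
  }
  recs <- batch$records
  for (i in seq_along(recs)) {
    if (inherits(recs[[i]], "transport_record")) {
      write_track(recs[[i]], file.path(dir, sprintf("run_%03d", i)))
    }
  }
  .write_tsv(batch$outcomes, file.path(dir, "outcomes.tsv"))
  .write_tsv(as_tibble(batch$fpt), file.path(dir, "fpt.tsv"))
  if (!is.null(config)) save_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
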