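#' Read and write choice logs
#'
#' Choice logs are UTF-8 CSV files with columns `round`, `player`,
#' `option`, `payout_cent`, `bonus_cent` (name-keyed: column order is
#' irrelevant, missing mandatory columns are a schema error). Missed rounds
#' carry an empty `option` field.
#'
#' @param path file path.
#' @return `read_choices()`: a data frame in canonical column order.
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round", "player", "option", "payout_cent", "bonus_cent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_choices: missing column(s): ", paste(miss, collapse = ", "))
  df[, need]
}

#' @rdname read_choices
#' @param choices data frame of round choices.
#' @export
write_choices <- function(choices, path) {
  need <- c("round", "player", "option", "payout_cent", "bonus_cent")
  miss <- setdiff(need, names(choices))
  if (length(miss))
    stop("write_choices: missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(choices[, need], path, row.names = FALSE, quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read and write movement trajectories
#'
#' Trajectory CSVs hold one move event per row with columns `round`,
#' `event_index`, `player`, `from_q`, `from_r`, `to_q`, `to_r` (axial hex
#' coordinates, origin at the board center). On reading, events are ordered
#' and validated against the board (continuity, on-board cells); validation
#' errors name the offending row. Initial positions are taken from each
#' player's first departure cell unless supplied.
#'
#' @param path file path.
#' @param board a [hex_board()].
#' @param initial_positions optional data frame `player`, `q`, `r`; if
#'   `NULL`, derived from first `from_*` per player.
#' @return `read_trajectory()`: list with `moves` and `initial_positions`.
#' @export
read_trajectory <- function(path, board = hex_board(),
                            initial_positions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round", "event_index", "player", "from_q", "from_r",
            "to_q", "to_r")
  if (nrow(df) == 0L && is.null(initial_positions)) {
    warning("read_trajectory: empty trajectory file")
    empty <- as.data.frame(stats::setNames(rep(list(integer(0)), length(need)),
                                           need))
    return(list(moves = empty,
                initial_positions = data.frame(player = integer(0),
                                               q = integer(0),
                                               r = integer(0))))
  }
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_trajectory: missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$round, df$event_index), ]
  if (is.null(initial_positions)) {
    first <- df[!duplicated(df$player), ]
    initial_positions <- data.frame(player = first$player,
                                    q = first$from_q, r = first$from_r)
  }
  moves <- validate_trajectory(df, initial_positions, board)
  list(moves = moves, initial_positions = initial_positions)
}

#' @rdname read_trajectory
#' @param moves data frame of move events.
#' @export
write_trajectory <- function(moves, path) {
  need <- c("round", "event_index", "player", "from_q", "from_r",
            "to_q", "to_r")
  miss <- setdiff(need, names(moves))
  if (length(miss))
    stop("write_trajectory: missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(moves[, need], path, row.names = FALSE, quote = FALSE,
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a named list of tables to CSV files
#'
#' @param objects named list of data frames.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_tables <- function(objects, dir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(objects[[nm]], p, row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8", na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Configuration files mirror [sim_config()] field names exactly; `options`
#' is a table of `payout_cent` / `success_prob` (and optionally `role`),
#' `bonus` a mapping with `kind` and `additive_amount_cent`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("n_agents", "options", "epsilon", "n_iterations",
             "forced_exploration_iterations", "n_runs", "bonus", "seed",
             "bonus_in_update")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_sim_config: unknown field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$options)) {
    o <- as.data.frame(raw$options)
    raw$options <- if ("role" %in% names(o))
      option_set(o$payout_cent, o$success_prob, o$role)
    else option_set(o$payout_cent, o$success_prob)
  }
  if (!is.null(raw$bonus)) {
    b <- raw$bonus
    raw$bonus <- bonus_scheme(b$kind,
                              if (is.null(b$additive_amount_cent)) 3L
                              else b$additive_amount_cent)
  }
  do.call(sim_config, raw)
}

#' Run manifests for reproducibility
#'
#' `write_manifest()` snapshots a run: configuration, seed, package
#' version, timestamp and an MD5 checksum inventory of the output files.
#' `verify_manifest()` re-checksums the inventory; for deterministic stages
#' re-running with the manifest's config and seed must reproduce the files
#' byte-identically.
#'
#' @param config list or config object describing the run.
#' @param seed integer seed used.
#' @param files character vector of output file paths.
#' @param path manifest path (JSON).
#' @return `write_manifest()`: the path, invisibly. `verify_manifest()`:
#'   `TRUE` if all checksums match, otherwise `FALSE` with attribute
#'   `mismatches`.
#' @export
write_manifest <- function(config, seed, files, path) {
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "cohesim",
    version = as.character(utils::packageVersion("cohesim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = data.frame(path = names(sums), md5 = unname(sums)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
verify_manifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  files <- manifest$files
  now <- tools::md5sum(files$path)
  ok <- !is.na(now) & now == files$md5
  if (all(ok)) TRUE else structure(FALSE, mismatches = files$path[!ok])
}
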