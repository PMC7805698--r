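#' Load a task configuration from YAML
#'
#' Reads a YAML file with at least `task` and `seed` fields, fills task
#' defaults and validates. Unknown fields are rejected with the field
#' named in the message.
#'
#' @param path Path to a YAML configuration file.
#' @return A `task_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$task)) stop("config is missing the 'task' field")
  if (is.null(raw$seed)) stop("config is missing the 'seed' field")
  task <- raw$task
  seed <- raw$seed
  raw$task <- NULL
  raw$seed <- NULL
  # yaml reads vectors of length > 1 as lists; flatten plain numeric ones
  raw <- lapply(raw, function(v) {
    if (is.list(v) && length(v) && all(vapply(v, is.numeric, logical(1))) &&
        all(lengths(v) == 1L)) {
      unlist(v)
    } else v
  })
  do.call(task_config, c(list(task = task, seed = seed), raw))
}

#' Save a task configuration as YAML
#'
#' @param cfg A `task_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a run manifest and outputs for a task result
#'
#' Serializes the configuration, seed, package version, per-check
#' verdicts and the output-file inventory to `manifest.json` inside
#' `out_dir`, alongside the result's traces as TSV files. The manifest
#' plus the package version is sufficient to re-run the task
#' bit-identically.
#'
#' @param result A `task_result`.
#' @param out_dir Output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  flatten_traces <- function(traces, prefix = "") {
    for (nm in names(traces)) {
      tr <- traces[[nm]]
      if (is.data.frame(tr)) {
        f <- file.path(out_dir, paste0(prefix, nm, ".tsv"))
        write_trace(tr, f)
        files <<- c(files, basename(f))
      } else if (is.list(tr)) {
        flatten_traces(tr, paste0(prefix, nm, "_"))
      }
    }
  }
  flatten_traces(result$traces)
  manifest <- list(
    task = result$task,
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("latchmem")),
    config = unclass(result$config),
    verdicts = as.list(result$verdicts),
    passed = task_passed(result),
    files = files
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Summarize manifests from several runs into one table
#'
#' @param dirs Character vector of output directories containing
#'   `manifest.json` files.
#' @return Data frame with one row per manifest (task, seed, passed,
#'   number of checks).
#' @export
report_manifests <- function(dirs) {
  rows <- lapply(dirs, function(d) {
    f <- file.path(d, "manifest.json")
    if (!file.exists(f)) return(NULL)
    m <- jsonlite::read_json(f)
    data.frame(dir = d, task = m$task, seed = m$seed,
               passed = isTRUE(m$passed),
               n_checks = length(m$verdicts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Command-line entry point
#'
#' Implements `latchmem run <task|config.yaml> [--seed S] [--out DIR]`,
#' `latchmem sweep <task> --seeds S1,S2,... [--out DIR]` and
#' `latchmem report DIR...`. Exit status: 0 if all checks of all runs
#' passed, 2 if any check failed, 1 on usage or runtime error. All
#' data outputs go to the `--out` directory; messages go to stderr.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: latchmem run <task|config.yaml> [--seed S] [--out DIR]")
    message("       latchmem sweep <task> --seeds S1,S2,... [--out DIR]")
    message("       latchmem report DIR [DIR...]")
    message("tasks: ", paste(task_names(), collapse = ", "))
  }
  code <- tryCatch({
    if (length(argv) < 1) { usage(); return(invisible(1L)) }
    cmd <- argv[1]
    rest <- argv[-1]
    opt <- function(name, default = NULL) {
      i <- which(rest == paste0("--", name))
      if (length(i) == 1 && i < length(rest)) rest[i + 1] else default
    }
    positional <- {
      drop <- integer(0)
      for (nm in c("seed", "out", "seeds")) {
        i <- which(rest == paste0("--", nm))
        if (length(i) == 1) drop <- c(drop, i, i + 1)
      }
      if (length(drop)) rest[-drop] else rest
    }
    if (cmd == "run") {
      if (length(positional) != 1) { usage(); return(invisible(1L)) }
      target <- positional[1]
      out_dir <- opt("out", file.path("latchmem_out", target))
      cfg <- if (file.exists(target) && grepl("\\.ya?ml$", target)) {
        load_config(target)
      } else {
        if (!target %in% task_names()) {
          message("unknown task '", target, "'")
          usage()
          return(invisible(1L))
        }
        task_config(target, seed = as.integer(opt("seed", 1)))
      }
      res <- run_task(cfg)
      write_manifest(res, out_dir)
      message(sprintf("%s: %d/%d checks passed (manifest in %s)",
                      cfg$task, sum(res$verdicts), length(res$verdicts),
                      out_dir))
      if (task_passed(res)) 0L else 2L
    } else if (cmd == "sweep") {
      if (length(positional) != 1) { usage(); return(invisible(1L)) }
      task <- positional[1]
      if (!task %in% task_names()) {
        message("unknown task '", task, "'")
        usage()
        return(invisible(1L))
      }
      seeds <- as.integer(strsplit(opt("seeds", "1"), ",")[[1]])
      out_root <- opt("out", file.path("latchmem_out", task))
      ok <- TRUE
      for (s in seeds) {
        res <- run_task(task_config(task, seed = s))
        write_manifest(res, file.path(out_root, paste0("seed_", s)))
        ok <- ok && task_passed(res)
        message(sprintf("%s seed %d: %s", task, s,
                        if (task_passed(res)) "pass" else "FAIL"))
      }
      if (ok) 0L else 2L
    } else if (cmd == "report") {
      if (length(positional) < 1) { usage(); return(invisible(1L)) }
      tab <- report_manifests(positional)
      if (is.null(tab)) {
        message("no manifests found")
        return(invisible(1L))
      }
      writeLines(utils::capture.output(print(tab)))
      if (all(tab$passed)) 0L else 2L
    } else {
      usage()
      1L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
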