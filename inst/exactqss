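#!/usr/bin/env Rscript

# Thin command-line wrapper over the exactqss package.
#
#   exactqss fixtures --list | exactqss fixtures NAME [--eps E] [-o FILE]
#   exactqss moments MODEL --seed 0002 [--params a=1,b=2] [--json]
#   exactqss balance MODEL
#   exactqss qss MODEL --species DA [--json]
#   exactqss reduce MODEL --mode emb|amb [-o FILE]
#   exactqss simulate MODEL --t-end 8 [--runs N] [--seed S] [--grid a:b:dt] [-o FILE]
#   exactqss periods TRAJ.csv --species M --segments 100

suppressPackageStartupMessages(library(exactqss))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0L) stop("usage: exactqss <fixtures|moments|balance|qss|reduce|simulate|periods> ...")
cmd <- argv[1L]
argv <- argv[-1L]

getopt <- function(flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) == 0L) return(default)
  argv[i[1L] + 1L]
}
hasflag <- function(flag) flag %in% argv
positional <- function() {
  drop <- integer(0)
  i <- 1L
  while (i <= length(argv)) {
    if (startsWith(argv[i], "-")) {
      drop <- c(drop, i, if (i < length(argv) && !startsWith(argv[i + 1L], "-")) i + 1L)
      i <- i + 2L
    } else i <- i + 1L
  }
  if (length(drop) > 0L) argv[-drop] else argv
}
parse_params <- function(txt) {
  if (is.null(txt)) return(list())
  parts <- strsplit(strsplit(txt, ",")[[1L]], "=")
  stats::setNames(lapply(parts, function(p) as.numeric(p[2L])),
                  vapply(parts, `[[`, character(1), 1L))
}
load_model <- function(path) {
  if (path %in% c("feedforward", "negative_feedback", "oscillator", "decoy"))
    build_example(path) else model_from_json(path)
}

if (cmd == "fixtures") {
  if (hasflag("--list")) {
    cat("feedforward\nnegative_feedback\noscillator\ndecoy\n")
  } else {
    nm <- positional()[1L]
    eps <- getopt("--eps")
    net <- if (is.null(eps)) build_example(nm) else build_example(nm, eps = as.numeric(eps))
    out <- getopt("-o")
    if (is.null(out)) cat(model_to_json(net), "\n") else model_to_json(net, out)
  }
} else if (cmd == "moments") {
  net <- load_model(positional()[1L])
  seed_str <- getopt("--seed")
  if (is.null(seed_str)) stop("--seed (moment digit string) is required")
  u <- as.integer(strsplit(seed_str, "")[[1L]])
  sys <- build_closure(list(u), net)
  if (inherits(sys, "closure_failure")) { print(sys); quit(status = 1L) }
  pars <- parse_params(getopt("--params"))
  sm <- tryCatch(stationary_moments(sys, pars, as_numeric = TRUE),
                 error = function(e) NULL)
  if (hasflag("--json")) {
    cat(jsonlite::toJSON(list(moments = moment_strings(sys),
                              n = length(moment_strings(sys)),
                              max_order = max(vapply(sys$moments, sum, integer(1))),
                              stationary = sm),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA), "\n")
  } else {
    print(sys)
    cat("moments:", paste(moment_strings(sys), collapse = " "), "\n")
    if (!is.null(sm)) for (k in names(sm)) cat(sprintf("  <%s> = %g\n", k, sm[[k]]))
  }
} else if (cmd == "balance") {
  net <- load_model(positional()[1L])
  p <- split_fast_slow(net)
  sub <- exactqss:::fast_subnetwork(net, p, symbolic_slow = FALSE)
  print(analyze_structure(sub))
} else if (cmd == "qss") {
  net <- load_model(positional()[1L])
  spn <- getopt("--species")
  if (is.null(spn)) stop("--species is required")
  q <- derive_qss(net, list(stats::setNames(1L, spn)), mode = "emb",
                  params = parse_params(getopt("--params")))[[1L]]
  if (q$kind == "constant") {
    cat("constant QSS:", exactqss:::q_to_num(q$value), "\n")
  } else if (hasflag("--json")) {
    td <- tidy(q$qss)
    cat(jsonlite::toJSON(td, dataframe = "rows", pretty = TRUE, digits = NA), "\n")
  } else {
    print(q$qss)
    print(tidy(q$qss), n = Inf)
  }
} else if (cmd == "reduce") {
  net <- load_model(positional()[1L])
  mode <- getopt("--mode", "emb")
  red <- build_reduced_model(net, mode = mode,
                             params = parse_params(getopt("--params")))
  print(red)
  out <- getopt("-o")
  if (!is.null(out)) {
    saveRDS_free <- tidy(red)
    utils::write.csv(saveRDS_free, out, row.names = FALSE)
    cat("reaction table written to ", out, "\n")
  }
} else if (cmd == "simulate") {
  net <- load_model(positional()[1L])
  t_end <- as.numeric(getopt("--t-end", "10"))
  runs <- as.integer(getopt("--runs", "1"))
  seed <- as.integer(getopt("--seed", "1"))
  g <- getopt("--grid")
  grid <- if (is.null(g)) seq(0, t_end, length.out = 201L) else {
    v <- as.numeric(strsplit(g, ":")[[1L]])
    seq(v[1L], v[2L], v[3L])
  }
  out <- getopt("-o")
  if (runs == 1L) {
    tr <- gillespie_direct(net, t_end, seed = seed, grid = grid)
    if (is.null(out)) print(tr) else utils::write.csv(tr, out, row.names = FALSE)
  } else {
    es <- ensemble_summary(net, n_runs = runs, t_end = t_end, grid = grid, seed = seed)
    if (is.null(out)) print(es) else utils::write.csv(es, out, row.names = FALSE)
  }
  if (!is.null(out)) cat("written to ", out, "\n")
} else if (cmd == "periods") {
  tr <- utils::read.csv(positional()[1L])
  ps <- period_analysis(tibble::as_tibble(tr), getopt("--species", "M"),
                        n_segments = as.integer(getopt("--segments", "100")))
  print(ps)
} else {
  stop("unknown subcommand: ", cmd)
}
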