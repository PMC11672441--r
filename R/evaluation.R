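#' Build nested noisy query sets
#'
#' For each eligible target disease and replicate, draws a base query of
#' `query_size` symptoms from the target's own symptoms (Noise0; the full
#' set when the target has exactly `query_size`), then derives each higher
#' noise level from the previous one by replacing one uniformly chosen
#' remaining relevant symptom with a uniformly chosen symptom *not*
#' associated with the target (and not already in the query). A level-L
#' query therefore carries exactly L unrelated symptoms, and the relevant
#' symptoms at level L+1 are a strict subset of level L's.
#'
#' Targets with fewer than `query_size` symptoms are excluded with a
#' warning; when more targets are eligible than `protocol$n_targets`, a
#' seeded uniform subsample is evaluated.
#'
#' @param kb A `knowledge_base`.
#' @param protocol A [noise_protocol()].
#' @return An object of class `noise_query_sets`: a list with `targets`
#'   and `queries` (one record per target x replicate, holding the query
#'   data frame and replacement provenance for every requested level).
#' @export
build_noise_sets <- function(kb, protocol = noise_protocol()) {
  qs <- protocol$query_size
  all_sym <- kb$symptoms$symptom_id
  if (length(all_sym) < qs + 1L)
    stop("knowledge base has too few symptoms for the protocol", call. = FALSE)
  elig <- eligible_targets(kb, protocol$min_symptoms)
  sizes <- kb$derived$n_symptoms_per_disease[match(elig, kb$diseases$disease_id)]
  short <- elig[sizes < qs]
  if (length(short) > 0L) {
    warning("excluding ", length(short),
            " target(s) with fewer than ", qs, " symptoms", call. = FALSE)
    elig <- elig[sizes >= qs]
  }
  if (length(elig) == 0L)
    stop("no eligible target supports the query size", call. = FALSE)
  maxlev <- max(protocol$levels)
  withr::with_seed(protocol$seed, {
    if (!is.null(protocol$n_targets) && length(elig) > protocol$n_targets)
      elig <- sort(sample(elig, protocol$n_targets))
    queries <- vector("list", length(elig) * protocol$replicates)
    i <- 0L
    for (t in elig) {
      ti <- match(t, kb$diseases$disease_id)
      S_t <- all_sym[kb$incidence[ti, ] > 0]
      pool <- setdiff(all_sym, S_t)
      for (r in seq_len(protocol$replicates)) {
        base <- if (length(S_t) == qs) S_t else sort(.sample1(S_t, qs))
        levels_syms <- list(`0` = base)
        relevant <- base
        cur <- base
        prov <- list()
        for (L in seq_len(maxlev)) {
          out <- .sample1(relevant, 1L)
          repl <- .sample1(setdiff(pool, cur), 1L)
          cur[cur == out] <- repl
          relevant <- setdiff(relevant, out)
          prov[[L]] <- c(removed = out, added = repl)
          levels_syms[[as.character(L)]] <- cur
        }
        i <- i + 1L
        queries[[i]] <- list(
          target = t, replicate = r,
          symptoms = levels_syms[as.character(protocol$levels)],
          provenance = prov)
      }
    }
  })
  structure(list(targets = elig, protocol = protocol, queries = queries),
            class = "noise_query_sets")
}

# sample() with surprise-free single-element behavior
.sample1 <- function(x, n) x[sample.int(length(x), n)]

#' Top-k hit test
#'
#' Whether the target disease appears among the first `min(k, length)`
#' entries of a ranked diagnosis.
#'
#' @param result A `ranked_diagnosis` (or data frame with `disease_id`).
#' @param target A disease id.
#' @param k Cutoff rank (>= 1).
#' @return Logical scalar.
#' @export
top_k_hit <- function(result, target, k) {
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  nrow(result) > 0L && target %in% result$disease_id[seq_len(min(k, nrow(result)))]
}

#' Run the noise-robustness benchmark
#'
#' Builds one shared collection of noisy query sets (so every engine sees
#' identical inputs), runs each engine on every query, and reports top-1
#' and top-3 accuracy (percent of targets hit) per engine and noise
#' level, averaged over replicates with the replicate standard deviation.
#' An engine failure on a query is recorded as a miss and the run
#' continues.
#'
#' @param kb A `knowledge_base`.
#' @param engines Engine names (subset of [list_engines()]) or a list of
#'   engine objects from [get_engine()].
#' @param protocol A [noise_protocol()].
#' @param config A [fuzzy_config()] passed to each engine.
#' @return A `noise_benchmark_report`: data frame with columns `engine`,
#'   `level`, `top1`, `top3`, `n_targets`, `sd1`, `sd3`, with the seed,
#'   a configuration fingerprint and the per-replicate accuracies as
#'   attributes.
#' @export
run_benchmark <- function(kb, engines = list_engines(),
                          protocol = noise_protocol(),
                          config = fuzzy_config()) {
  if (is.character(engines))
    engines <- lapply(engines, get_engine, kb = kb, config = config)
  sets <- build_noise_sets(kb, protocol)
  nt <- length(sets$targets)
  rows <- list()
  percell <- list()
  for (eng in engines) {
    for (L in protocol$levels) {
      hit1 <- hit3 <- matrix(FALSE, nt, protocol$replicates)
      for (q in sets$queries) {
        res <- tryCatch(
          eng$infer(kb, query_from_symptoms(kb, q$symptoms[[as.character(L)]]),
                    config),
          error = function(e) {
            warning(sprintf("engine '%s' failed on target %d (level %d): %s",
                            eng$name, q$target, L, conditionMessage(e)),
                    call. = FALSE)
            NULL
          })
        ti <- match(q$target, sets$targets)
        if (!is.null(res)) {
          hit1[ti, q$replicate] <- top_k_hit(res, q$target, 1L)
          hit3[ti, q$replicate] <- top_k_hit(res, q$target, 3L)
        }
      }
      acc1 <- 100 * colMeans(hit1)
      acc3 <- 100 * colMeans(hit3)
      rows[[length(rows) + 1L]] <- data.frame(
        engine = eng$name, level = L,
        top1 = mean(acc1), top3 = mean(acc3), n_targets = nt,
        sd1 = if (length(acc1) > 1L) stats::sd(acc1) else 0,
        sd3 = if (length(acc3) > 1L) stats::sd(acc3) else 0,
        stringsAsFactors = FALSE)
      percell[[paste(eng$name, L, sep = ".")]] <-
        list(top1 = acc1, top3 = acc3)
    }
  }
  rep <- do.call(rbind, rows)
  structure(rep,
            class = c("noise_benchmark_report", "data.frame"),
            seed = protocol$seed,
            config_fingerprint = .protocol_fingerprint(protocol, config),
            replicate_accuracy = percell)
}

.protocol_fingerprint <- function(protocol, config) {
  paste0("qs", protocol$query_size,
         "-L", paste(protocol$levels, collapse = ""),
         "-r", protocol$replicates, "-s", protocol$seed,
         "-min", protocol$min_symptoms,
         "-nt", if (is.null(protocol$n_targets)) "all" else protocol$n_targets,
         "-m", format(config$m))
}

#' Write a benchmark report
#'
#' Serializes a `noise_benchmark_report` as JSON (full metadata) and/or a
#' CSV matrix (`engine,level,top1,top3,n,sd1,sd3`).
#'
#' @param report A `noise_benchmark_report`.
#' @param path Output path without extension.
#' @param formats Subset of `c("json", "csv")`.
#' @return Paths written, invisibly.
#' @export
write_report <- function(report, path, formats = c("json", "csv")) {
  out <- character(0)
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 6))
  if ("json" %in% formats) {
    f <- paste0(path, ".json")
    jsonlite::write_json(
      list(seed = attr(report, "seed"),
           config = attr(report, "config_fingerprint"),
           results = df),
      f, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out <- c(out, f)
  }
  if ("csv" %in% formats) {
    f <- paste0(path, ".csv")
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    out <- c(out, f)
  }
  invisible(out)
}

#' @export
print.noise_benchmark_report <- function(x, ...) {
  cat("Noise-robustness benchmark (top-1 / top-3 accuracy, %)\n")
  cat(sprintf("seed %d, %s\n", attr(x, "seed"), attr(x, "config_fingerprint")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot accuracy against noise level
#'
#' Base-graphics line plot of mean top-k accuracy per engine over noise
#' levels.
#'
#' @param x A `noise_benchmark_report`.
#' @param metric `"top1"` or `"top3"`.
#' @param ... Passed to [graphics::matplot()].
#' @return The report, invisibly.
#' @export
plot.noise_benchmark_report <- function(x, metric = c("top1", "top3"), ...) {
  metric <- match.arg(metric)
  df <- as.data.frame(x)
  engines <- unique(df$engine)
  levels <- sort(unique(df$level))
  M <- sapply(engines, function(e)
    df[[metric]][df$engine == e][order(df$level[df$engine == e])])
  graphics::matplot(levels, M, type = "b", pch = seq_along(engines),
                    lty = 1, xlab = "noise level",
                    ylab = sprintf("%s accuracy (%%)", metric),
                    ylim = c(0, 100), ...)
  graphics::legend("bottomleft", legend = engines, pch = seq_along(engines),
                   col = seq_along(engines), lty = 1, bty = "n")
  invisible(x)
}
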