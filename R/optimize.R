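# The optimization round loop: score the seed pool, then per round fit the
# surrogate on everything evaluated so far, propose a batch by acquisition,
# predict structures, score both objectives, and grow the pool.

# Reference point: componentwise minimum of the observed canonical objectives
# minus `margin` times the observed range (range 0 falls back to 1).
reference_point <- function(canonical, margin = 0.1) {
  lo <- apply(canonical, 2, min)
  rg <- apply(canonical, 2, function(v) max(v) - min(v))
  rg[rg <= 0] <- 1
  lo - margin * rg
}

#' Propose a batch of new peptide sequences
#'
#' Generates up to `n_candidates` unique mutants of the current
#' Pareto-archive parents (cycled round-robin, `mutations_per_proposal`
#' substitutions each), excludes sequences already in the pool, scores the
#' survivors with the noisy-hypervolume-improvement acquisition, and returns
#' the top `batch_size`, ties broken toward the lexicographically smaller
#' sequence. With `config$proposer = "random"` the acquisition step is
#' replaced by uniform-random selection (the baseline arm) and parents are
#' the whole scored pool. If fewer novel sequences than `batch_size` can be
#' produced after bounded retries, a smaller batch is returned with a
#' warning.
#'
#' @param pool data frame of evaluated candidates: columns `sequence`,
#'   `status`, and canonical objective columns `c1`, `c2`.
#' @param gp fitted `gp_surrogate` (ignored for the random proposer).
#' @param config a [bo_config()].
#' @param seed RNG seed for generation, acquisition draws and random
#'   selection.
#' @return data frame with columns `sequence`, `parent`, `acquisition`; for
#'   the nehvi proposer the full scored candidate list is attached as the
#'   `"all_candidates"` attribute.
#' @export
propose_batch <- function(pool, gp, config, seed = NULL) {
  scored <- pool[pool$status == "ok", , drop = FALSE]
  if (nrow(scored) == 0L)
    stop_pf("pool has no scored candidates", class = "pepforge_bad_pool")
  canon <- as.matrix(scored[, c("c1", "c2")])
  parents <- if (config$proposer == "random") scored$sequence
             else scored$sequence[pareto_front(canon)]
  parents <- sort(unique(parents))
  cand <- character(0)
  cand_parent <- character(0)
  with_seed(seed, {
    attempts <- 0L
    max_attempts <- 4L * config$n_candidates
    k <- 0L
    while (length(cand) < config$n_candidates && attempts < max_attempts) {
      p <- parents[(k %% length(parents)) + 1L]
      k <- k + 1L
      s <- mutate_sequence(p, config$mutations_per_proposal)
      if (!(s %in% pool$sequence) && !(s %in% cand)) {
        cand <- c(cand, s)
        cand_parent <- c(cand_parent, p)
      }
      attempts <- attempts + 1L
    }
  })
  if (!length(cand)) {
    warning("no novel candidate sequences could be generated; empty batch",
            call. = FALSE)
    return(data.frame(sequence = character(0), parent = character(0),
                      acquisition = numeric(0)))
  }
  if (config$proposer == "random") {
    sel <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                     sample.int(length(cand),
                                min(config$batch_size, length(cand))))
    out <- data.frame(sequence = cand[sel], parent = cand_parent[sel],
                      acquisition = NA_real_)
  } else {
    if (!inherits(gp, "gp_surrogate"))
      stop_pf("a fitted gp_surrogate is required for the nehvi proposer",
              class = "pepforge_gp_error")
    max_len <- config$max_len %||% max(nchar(c(pool$sequence, cand)))
    Xobs <- embed_matrix(scored$sequence, max_len)
    Xc <- embed_matrix(cand, max_len)
    ref <- reference_point(canon, config$ref_margin)
    acq <- nehvi(Xc, gp, Xobs, ref, n_mc = config$n_mc,
                 seed = if (is.null(seed)) NULL else seed + 1L)
    ord <- order(-acq, cand)
    sel <- ord[seq_len(min(config$batch_size, length(cand)))]
    out <- data.frame(sequence = cand[sel], parent = cand_parent[sel],
                      acquisition = acq[sel])
    attr(out, "all_candidates") <- data.frame(sequence = cand,
                                              parent = cand_parent,
                                              acquisition = acq)
  }
  if (nrow(out) < config$batch_size)
    warning(sprintf("only %d of %d requested novel sequences proposed",
                    nrow(out), config$batch_size), call. = FALSE)
  rownames(out) <- NULL
  out
}

score_candidates <- function(seqs, parents, round, provider, scorer, config) {
  n <- length(seqs)
  obj <- matrix(NA_real_, n, 2)
  status <- character(n)
  structures <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      st <- predict_structure(provider, seqs[i])
      list(st = st, vals = scorer(st))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "failed"
    } else {
      status[i] <- "ok"
      obj[i, ] <- res$vals
      structures[[i]] <- res$st
    }
  }
  canon <- canonical_objectives(obj, config$directions)
  rec <- data.frame(sequence = seqs, round = round, parent = parents,
                    status = status, o1 = obj[, 1], o2 = obj[, 2],
                    c1 = canon[, 1], c2 = canon[, 2],
                    stringsAsFactors = FALSE)
  names(rec)[names(rec) == "o1"] <- config$objectives[1]
  names(rec)[names(rec) == "o2"] <- config$objectives[2]
  names(structures) <- seqs
  list(records = rec, structures = structures)
}

archive_hypervolume <- function(records, ref) {
  ok <- records[records$status == "ok", , drop = FALSE]
  pts <- as.matrix(ok[, c("c1", "c2")])
  keep <- pts[, 1] >= ref[1] & pts[, 2] >= ref[2]
  if (!any(keep)) return(0)
  hypervolume_2d(pts[keep, , drop = FALSE], ref)
}

round_summary <- function(records, round, ref, config) {
  batch <- records[records$round == round & records$status == "ok", ,
                   drop = FALSE]
  stat <- function(col, f) if (nrow(batch)) f(batch[[col]]) else NA_real_
  o <- config$objectives
  data.frame(
    round = round, n_evaluated = nrow(batch),
    setNames(list(stat(o[1], min), stat(o[1], max), stat(o[1], mean),
                  stat(o[2], min), stat(o[2], max), stat(o[2], mean)),
             c(paste0(o[1], c("_min", "_max", "_mean")),
               paste0(o[2], c("_min", "_max", "_mean")))),
    hypervolume = archive_hypervolume(records, ref),
    check.names = FALSE)
}

#' Run the structure-guided peptide optimization loop
#'
#' Seeds a pool of mutated peptides, scores them on the two configured
#' structural objectives via the structure provider, then iterates: fit the
#' Gaussian-process surrogate on every scored candidate, propose a batch by
#' noisy-hypervolume-improvement, predict structures and score the batch,
#' and append it to the pool. Per-round minimum/maximum/mean of both
#' objectives and the archive hypervolume (against the reference point fixed
#' after scoring the seeds) are logged. Provider failures mark the candidate
#' `failed` and the run continues. Fully deterministic for a given config.
#'
#' @param native_complex the native protein-peptide `complex_structure`; the
#'   default provider threads candidate sequences onto it.
#' @param config a [bo_config()].
#' @param provider optional `structure_provider` (default: template threading
#'   on `native_complex`).
#' @return object of class `pep_archive`: candidate table, per-round summary,
#'   kept structures, config.
#' @export
run_optimization <- function(native_complex, config = bo_config(),
                             provider = NULL) {
  stopifnot(inherits(config, "bo_config"))
  validate_complex(native_complex)
  provider <- provider %||% template_provider(native_complex)
  native_pep <- chain_sequence(native_complex, "peptide")
  if (is.null(config$max_len)) config$max_len <- nchar(native_pep)
  scorer <- objective_scorer(config)
  base_seed <- as.integer(config$seed)

  if (!is.null(config$seed_fasta)) {
    fa <- seqinr::read.fasta(config$seed_fasta, seqtype = "AA",
                             as.string = TRUE)
    seqs <- unique(toupper(vapply(fa, as.character, character(1))))
    if (config$include_native) seqs <- unique(c(native_pep, seqs))
    for (s in seqs) validate_peptide_sequence(s, "seed_fasta sequence")
    seeds <- data.frame(sequence = seqs, round = 0L, parent = native_pep,
                        stringsAsFactors = FALSE)
  } else {
    seeds <- seed_pool(native_pep, config$n_seeds, config$mutations_per_seed,
                       seed = base_seed + 1L,
                       include_native = config$include_native)
  }
  sc <- score_candidates(seeds$sequence, seeds$parent, 0L, provider, scorer,
                         config)
  records <- sc$records
  structures <- sc$structures
  ok <- records[records$status == "ok", , drop = FALSE]
  if (nrow(ok) < 2)
    stop_pf("fewer than two seeds could be scored; cannot optimize",
            class = "pepforge_provider_error")
  ref0 <- reference_point(as.matrix(ok[, c("c1", "c2")]), config$ref_margin)
  summary_tab <- round_summary(records, 0L, ref0, config)

  for (r in seq_len(config$n_rounds)) {
    scored <- records[records$status == "ok", , drop = FALSE]
    gp <- NULL
    if (config$proposer == "nehvi") {
      X <- embed_matrix(scored$sequence, config$max_len)
      gp <- fit_gp(X, as.matrix(scored[, c("c1", "c2")]))
    }
    batch <- propose_batch(records, gp, config,
                           seed = base_seed + 100L * r)
    if (nrow(batch)) {
      sb <- score_candidates(batch$sequence, batch$parent, r, provider,
                             scorer, config)
      records <- rbind(records, sb$records)
      structures <- c(structures, sb$structures)
    }
    summary_tab <- rbind(summary_tab, round_summary(records, r, ref0, config))
  }
  rownames(records) <- NULL
  rownames(summary_tab) <- NULL
  structure(list(candidates = records, summary = summary_tab,
                 structures = structures, config = config,
                 native_peptide = native_pep, reference_point = ref0,
                 provider_label = provider$label),
            class = "pep_archive")
}

#' @export
print.pep_archive <- function(x, ...) {
  ok <- sum(x$candidates$status == "ok")
  cat(sprintf("<pep_archive> %d candidates (%d scored) over %d rounds\n",
              nrow(x$candidates), ok, max(x$candidates$round)))
  cat(sprintf("  objectives: %s (%s), %s (%s)\n",
              x$config$objectives[1], x$config$directions[1],
              x$config$objectives[2], x$config$directions[2]))
  cat(sprintf("  final archive hypervolume: %.4g\n",
              x$summary$hypervolume[nrow(x$summary)]))
  invisible(x)
}

#' @export
summary.pep_archive <- function(object, ...) {
  cat(sprintf("Optimization of peptide '%s' (%s)\n", object$native_peptide,
              object$provider_label))
  print(object$summary, row.names = FALSE, digits = 4)
  ok <- object$candidates[object$candidates$status == "ok", , drop = FALSE]
  idx <- pareto_front(as.matrix(ok[, c("c1", "c2")]))
  cat(sprintf("\nPareto archive (%d sequences):\n", length(idx)))
  print(ok[idx, c("sequence", "round", object$config$objectives)],
        row.names = FALSE, digits = 4)
  invisible(object$summary)
}

#' Per-round objective trends
#'
#' Plots the per-round minimum, mean and maximum of each objective plus the
#' archive hypervolume trace.
#'
#' @param x a `pep_archive`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pep_archive <- function(x, ...) {
  s <- x$summary
  o <- x$config$objectives
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (obj in o) {
    cols <- paste0(obj, c("_min", "_mean", "_max"))
    graphics::matplot(s$round, as.matrix(s[, cols]), type = "l", lty = c(2, 1, 2),
                      col = c("grey50", "black", "grey50"),
                      xlab = "round", ylab = obj, main = obj, ...)
  }
  graphics::plot(s$round, s$hypervolume, type = "s", xlab = "round",
                 ylab = "hypervolume", main = "archive hypervolume")
  invisible(x)
}

#' Write an optimization archive to disk
#'
#' Tab-separated candidate and per-round summary tables plus the evaluated
#' peptide set as FASTA. Output is deterministic: identical runs produce
#' byte-identical files.
#'
#' @param archive a `pep_archive`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_archive <- function(archive, dir) {
  stopifnot(inherits(archive, "pep_archive"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    df
  }
  utils::write.table(fmt(archive$candidates),
                     file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(archive$summary), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- archive$candidates[archive$candidates$status == "ok", , drop = FALSE]
  seqinr::write.fasta(as.list(strsplit(ok$sequence, "")),
                      names = sprintf("cand_r%d_%s", ok$round, ok$sequence),
                      file.out = file.path(dir, "peptides.fasta"))
  invisible(dir)
}
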