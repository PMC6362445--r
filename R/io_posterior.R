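#' Write posterior draws to disk
#'
#' Serializes an `occ_draws` object as a columnar CSV (one row per chain x
#' retained iteration, one column per scalar parameter, plus any per-site
#' richness draws) together with a YAML metadata sidecar
#' (`<path>.meta.yaml`).  The round-trip through [read_posterior()] is
#' lossless for chains, iteration indices and parameter names.
#'
#' @param draws an `occ_draws`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_posterior <- function(draws, path) {
  stopifnot(inherits(draws, "occ_draws"))
  if (!length(draws$draws) || !nrow(draws$draws[[1]])) {
    stop("empty draws object")
  }
  tabs <- lapply(seq_along(draws$draws), function(ch) {
    m <- draws$draws[[ch]]
    out <- data.frame(chain = ch, iteration = seq_len(nrow(m)))
    out <- cbind(out, as.data.frame(m, check.names = FALSE))
    if (!is.null(draws$nsite)) {
      ns <- draws$nsite[[ch]]
      colnames(ns) <- sprintf("Nsite[%d]", seq_len(ncol(ns)))
      out <- cbind(out, as.data.frame(ns, check.names = FALSE))
    }
    out
  })
  tab <- do.call(rbind, tabs)
  # parameter names contain commas (e.g. delta[0,1]), so headers must be
  # quoted
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  meta <- draws$meta
  meta$accept <- lapply(meta$accept, as.list)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read posterior draws from disk
#'
#' @param path CSV written by [write_posterior()].
#' @return an `occ_draws`.
#' @export
read_posterior <- function(path) {
  if (!file.exists(path)) stop("posterior file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("chain", "iteration")
  if (!all(need %in% names(tab)) || !nrow(tab)) {
    stop("not a posterior draw table (or partial file): ", path)
  }
  chains <- sort(unique(tab$chain))
  nsite_cols <- grep("^Nsite\\[", names(tab), value = TRUE)
  par_cols <- setdiff(names(tab), c(need, nsite_cols))
  lens <- table(tab$chain)
  if (length(unique(lens)) != 1) {
    stop("partial posterior file: unequal chain lengths in ", path)
  }
  draws <- lapply(chains, function(ch) {
    sub <- tab[tab$chain == ch, , drop = FALSE]
    sub <- sub[order(sub$iteration), , drop = FALSE]
    if (!identical(sub$iteration, seq_len(nrow(sub)))) {
      stop("partial posterior file: missing iterations in chain ", ch)
    }
    as.matrix(sub[, par_cols, drop = FALSE])
  })
  nsite <- if (length(nsite_cols)) {
    lapply(chains, function(ch) {
      sub <- tab[tab$chain == ch, , drop = FALSE]
      sub <- sub[order(sub$iteration), , drop = FALSE]
      unname(as.matrix(sub[, nsite_cols, drop = FALSE]))
    })
  } else NULL
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  if (!is.null(meta$n_chains) && meta$n_chains != length(chains)) {
    stop("partial posterior file: expected ", meta$n_chains,
         " chains, found ", length(chains))
  }
  meta$n_chains <- length(chains)
  structure(list(draws = draws, nsite = nsite, meta = meta),
            class = "occ_draws")
}
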