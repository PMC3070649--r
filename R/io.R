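#' Export an expanded network
#'
#' GraphML and DOT exports carry the node `kind` attribute (original /
#' complementary / composite); the TSV export is a two-column edge list.
#' GraphML files re-import losslessly via [read_graphml_kinds()].
#'
#' @param xnet an `expanded_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(xnet, path) {
  igraph::write_graph(as_igraph(xnet), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_dot <- function(xnet, path) {
  g <- as_igraph(xnet)
  # igraph's DOT writer ignores vertex attributes; encode kind as a comment header
  igraph::write_graph(g, path, format = "dot")
  hdr <- c("// node kinds:",
           sprintf("// %s\t%s", xnet$nodes$id, xnet$nodes$kind))
  writeLines(c(hdr, readLines(path, warn = FALSE)), path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_tsv <- function(xnet, path) {
  utils::write.table(as.data.frame(xnet$edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_graphml
#' @return `read_graphml_kinds()`: tibble with columns `id`, `kind`.
#' @export
read_graphml_kinds <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  tibble::tibble(id = igraph::V(g)$name, kind = igraph::V(g)$kind)
}

#' Command-line interface
#'
#' Thin shell entry point over the package's functions; the `exec/esmnet`
#' script forwards to this. Subcommands:
#' \describe{
#'   \item{expand}{`esmnet expand [--no-prune] [--deep-negation] [--format graphml|dot|tsv] [--out F] rules`}
#'   \item{esms}{`esmnet esms [--mode ilp|mult|max] [--out F] rules` (count; `--list` enumerates)}
#'   \item{shortest}{`esmnet shortest rules`}
#'   \item{cascade}{`esmnet cascade --remove v1,v2 rules`}
#'   \item{rank}{`esmnet rank [--pairs] [--mode ilp|mult|max] [--out F] rules`}
#'   \item{simulate}{`esmnet simulate [--scheme synchronous|asynchronous] [--clamp v=0,w=1] [--horizon N] [--replicates N] [--seed N] rules`}
#'   \item{validate}{`esmnet validate [--seed N] [--out F] rules` (ROC of all measures vs dynamics)}
#'   \item{generate}{`esmnet generate [--n N] [--inhibitory p] [--and p] [--seed N] [--out F]`}
#' }
#' Exit status 0 on success, 2 on usage or input errors.
#'
#' @param argv character vector of arguments (default: the process's).
#' @return exit status, invisibly.
#' @export
esm_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: esmnet <expand|esms|shortest|cascade|rank|simulate|validate|generate> [options] [rules-file]\n")
  }
  emit <- function(lines, out) {
    if (is.null(out)) cat(lines, sep = "\n") else writeLines(lines, out)
  }
  status <- tryCatch({
    if (!length(argv)) { usage(); return(invisible(2L)) }
    cmd <- argv[[1L]]
    rest <- argv[-1L]
    opt <- list()
    pos <- character(0)
    i <- 1L
    flags0 <- c("--no-prune", "--deep-negation", "--pairs", "--list")
    while (i <= length(rest)) {
      a <- rest[[i]]
      if (a %in% flags0) {
        opt[[sub("^--", "", a)]] <- TRUE
      } else if (grepl("^--", a)) {
        if (i == length(rest)) stop("flag ", a, " needs a value", call. = FALSE)
        opt[[sub("^--", "", a)]] <- rest[[i + 1L]]
        i <- i + 1L
      } else {
        pos <- c(pos, a)
      }
      i <- i + 1L
    }
    out <- opt$out
    mode_of <- function(m) {
      switch(m %||% "ilp", ilp = "exact", exact = "exact",
             mult = "multiplication", max = "max",
             stop("unknown --mode: ", m, call. = FALSE))
    }
    need_net <- function() {
      if (length(pos) != 1L) stop("expected exactly one rules file", call. = FALSE)
      if (!file.exists(pos[[1L]])) stop("no such file: ", pos[[1L]], call. = FALSE)
      read_network(pos[[1L]])
    }
    switch(cmd,
      expand = {
        x <- expand(need_net(), prune = !isTRUE(opt$`no-prune`),
                    deep_negation = isTRUE(opt$`deep-negation`))
        fmt <- opt$format %||% "tsv"
        if (is.null(out)) {
          out2 <- tempfile(fileext = paste0(".", fmt))
        } else out2 <- out
        switch(fmt,
               graphml = write_graphml(x, out2),
               dot = write_dot(x, out2),
               tsv = write_edge_tsv(x, out2),
               stop("unknown --format: ", fmt, call. = FALSE))
        if (is.null(out)) { cat(readLines(out2, warn = FALSE), sep = "\n"); unlink(out2) }
      },
      esms = {
        x <- expand(need_net())
        m <- mode_of(opt$mode)
        if (isTRUE(opt$list)) {
          esms <- enumerate_esms(x)
          f <- out %||% tempfile(fileext = ".tsv")
          write_esms(esms, f)
          if (is.null(out)) { cat(readLines(f, warn = FALSE), sep = "\n"); unlink(f) }
        } else {
          emit(format(n_esms(x, m)), out)
        }
      },
      shortest = {
        e <- shortest_esm(expand(need_net()))
        emit(c(sprintf("length\t%s", format(e$length)),
               sprintf("size_all\t%d", e$size_all),
               sprintf("size_noncomposite\t%d", e$size_noncomposite),
               sprintf("nodes\t%s", paste(e$nodes$id, collapse = ","))), out)
      },
      cascade = {
        if (is.null(opt$remove)) stop("cascade requires --remove v1[,v2...]", call. = FALSE)
        res <- cascade_remove(expand(need_net()),
                              trimws(strsplit(opt$remove, ",")[[1L]]))
        emit(c(paste0("disrupted\t", paste(res$disrupted, collapse = ",")),
               paste0("transduces\t", residual_transduces(res))), out)
      },
      rank = {
        rep <- rank_components(need_net(), pairs = isTRUE(opt$pairs),
                               mode = mode_of(opt$mode))
        f <- out %||% tempfile(fileext = ".tsv")
        write_report(rep, f)
        if (is.null(out)) { cat(readLines(f, warn = FALSE), sep = "\n"); unlink(f) }
      },
      simulate = {
        clamp <- NULL
        if (!is.null(opt$clamp)) {
          kv <- strsplit(trimws(strsplit(opt$clamp, ",")[[1L]]), "=", fixed = TRUE)
          clamp <- stats::setNames(vapply(kv, function(p) p[[2L]], character(1)) == "1",
                                   vapply(kv, function(p) p[[1L]], character(1)))
        }
        tr <- simulate_boolean(need_net(), clamp = clamp,
                               scheme = opt$scheme %||% "synchronous",
                               horizon = as.integer(opt$horizon %||% "50"),
                               replicates = as.integer(opt$replicates %||% "100"),
                               seed = if (!is.null(opt$seed)) as.integer(opt$seed))
        emit(sprintf("%s\t%g", names(tr$on_frequency), tr$on_frequency), out)
      },
      validate = {
        net <- need_net()
        rep <- rank_components(net)
        truth <- classify_essential(net, seed = if (!is.null(opt$seed)) as.integer(opt$seed))
        ko <- truth[truth$kind == "knockout", ]
        roc <- roc_validation(rep, stats::setNames(ko$essential, ko$node))
        f <- out %||% tempfile(fileext = ".tsv")
        utils::write.table(as.data.frame(roc), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        if (is.null(out)) { cat(readLines(f, warn = FALSE), sep = "\n"); unlink(f) }
      },
      generate = {
        spec <- generator_spec(
          n_nodes = as.integer(opt$n %||% "12"),
          inhibitory_frac = as.numeric(opt$inhibitory %||% "0.2"),
          and_frac = as.numeric(opt$and %||% "0.3"),
          seed = if (!is.null(opt$seed)) as.integer(opt$seed))
        net <- generate_network(spec)
        emit(serialize_network(net), out)
      },
      { usage(); return(invisible(2L)) }
    )
    0L
  }, error = function(e) {
    message("esmnet: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
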