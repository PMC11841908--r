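# Plain-text serialization of fitted networks: a simple native format for
# auditability plus the standard Bayesian-network interchange format (BIF).

#' Write / read a fitted network in a plain-text native format
#'
#' One `node` line per variable (states), one `arc` line per arc, and one
#' `cpt` line per parent configuration with full-precision probabilities, so
#' a network is diffable and replayable.
#'
#' @param net a fitted `"bbn"`.
#' @param path file path.
#' @export
write_bbn <- function(net, path) {
  lines <- character(0)
  for (v in net$nodes)
    lines <- c(lines, paste("node", v, paste(net$states[[v]], collapse = " ")))
  a <- arcs(net)
  for (i in seq_len(nrow(a)))
    lines <- c(lines, paste("arc", a[i, 1], a[i, 2]))
  for (v in net$nodes) {
    pa <- net$parents[[v]]
    k <- length(net$states[[v]])
    cfgs <- if (length(pa))
      expand.grid(lapply(pa, function(p) net$states[[p]]),
                  stringsAsFactors = FALSE)
    else data.frame(row.names = 1)
    for (r in seq_len(nrow(cfgs))) {
      idx <- as.character(unlist(cfgs[r, ], use.names = FALSE))
      p <- do.call(`[`, c(list(net$cpt[[v]]), list(seq_len(k)), as.list(idx)))
      lines <- c(lines, paste("cpt", v,
                              if (length(pa)) paste(idx, collapse = ",") else "-",
                              paste(format(as.numeric(p), digits = 17), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bbn
#' @export
read_bbn <- function(path) {
  lines <- readLines(path)
  toks <- strsplit(lines, " +")
  states <- list(); arcs_m <- NULL
  for (t in toks[vapply(toks, function(t) t[1] == "node", TRUE)])
    states[[t[2]]] <- t[-(1:2)]
  for (t in toks[vapply(toks, function(t) t[1] == "arc", TRUE)])
    arcs_m <- rbind(arcs_m, t[2:3])
  nodes <- names(states)
  g <- bbn_dag(nodes, arcs_m)
  cpt <- lapply(nodes, function(v) {
    pa <- g$parents[[v]]
    dims <- c(length(states[[v]]), vapply(pa, function(p) length(states[[p]]), 0L))
    array(NA_real_, dim = dims, dimnames = c(list(states[[v]]),
                                             lapply(pa, function(p) states[[p]])))
  })
  names(cpt) <- nodes
  for (t in toks[vapply(toks, function(t) t[1] == "cpt", TRUE)]) {
    v <- t[2]
    p <- as.numeric(t[-(1:3)])
    if (t[3] == "-") cpt[[v]][] <- p
    else {
      idx <- strsplit(t[3], ",", fixed = TRUE)[[1]]
      ref <- do.call(`[<-`, c(list(cpt[[v]]),
                              list(seq_along(states[[v]])), as.list(idx),
                              list(value = p)))
      cpt[[v]] <- ref
    }
  }
  structure(list(nodes = nodes, parents = g$parents, states = states,
                 cpt = cpt, pseudocount = NA_real_), class = "bbn")
}

#' Export / import the Bayesian-network interchange format (BIF)
#'
#' Writes the network in the textual BIF dialect understood by most
#' Bayesian-network tools (`variable` and `probability` blocks); the reader
#' parses the same dialect back into a fitted `"bbn"`.
#'
#' @param net a fitted `"bbn"`.
#' @param path file path (conventionally `.bif`).
#' @param name network name recorded in the file.
#' @export
write_bif <- function(net, path, name = "surveybbn") {
  con <- file(path, "w"); on.exit(close(con))
  cat(sprintf("network %s {\n}\n", name), file = con)
  for (v in net$nodes)
    cat(sprintf("variable %s {\n  type discrete [ %d ] { %s };\n}\n",
                v, length(net$states[[v]]),
                paste(net$states[[v]], collapse = ", ")), file = con)
  for (v in net$nodes) {
    pa <- net$parents[[v]]
    k <- length(net$states[[v]])
    head <- if (length(pa)) sprintf("probability ( %s | %s ) {\n", v,
                                    paste(pa, collapse = ", "))
            else sprintf("probability ( %s ) {\n", v)
    cat(head, file = con)
    if (!length(pa)) {
      cat(sprintf("  table %s;\n",
                  paste(format(as.numeric(net$cpt[[v]]), digits = 17),
                        collapse = ", ")), file = con)
    } else {
      cfgs <- expand.grid(lapply(pa, function(p) net$states[[p]]),
                          stringsAsFactors = FALSE)
      for (r in seq_len(nrow(cfgs))) {
        idx <- as.character(unlist(cfgs[r, ], use.names = FALSE))
        p <- do.call(`[`, c(list(net$cpt[[v]]), list(seq_len(k)), as.list(idx)))
        cat(sprintf("  (%s) %s;\n", paste(idx, collapse = ", "),
                    paste(format(as.numeric(p), digits = 17), collapse = ", ")),
            file = con)
      }
    }
    cat("}\n", file = con)
  }
  invisible(path)
}

#' @rdname write_bif
#' @export
read_bif <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  states <- list()
  vm <- gregexpr("variable\\s+(\\S+)\\s*\\{[^}]*\\{([^}]*)\\}", txt, perl = TRUE)
  for (s in regmatches(txt, vm)[[1]]) {
    v <- sub("variable\\s+(\\S+).*", "\\1", s)
    lv <- sub(".*type discrete \\[\\s*\\d+\\s*\\]\\s*\\{([^}]*)\\}.*", "\\1", s)
    states[[v]] <- trimws(strsplit(lv, ",")[[1]])
  }
  pm <- gregexpr("probability\\s*\\(([^)]*)\\)\\s*\\{([^}]*)\\}", txt, perl = TRUE)
  blocks <- regmatches(txt, pm)[[1]]
  parents <- stats::setNames(rep(list(character(0)), length(states)), names(states))
  rows <- list()
  for (b in blocks) {
    head <- sub("probability\\s*\\(([^)]*)\\).*", "\\1", b)
    body <- sub("probability\\s*\\([^)]*\\)\\s*\\{", "", b)
    parts <- trimws(strsplit(head, "\\|")[[1]])
    v <- parts[1]
    pa <- if (length(parts) > 1) trimws(strsplit(parts[2], ",")[[1]]) else character(0)
    parents[[v]] <- pa
    rows[[v]] <- list(pa = pa, body = body)
  }
  nodes <- names(states)
  cpt <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    pa <- rows[[v]]$pa
    dims <- c(length(states[[v]]), vapply(pa, function(p) length(states[[p]]), 0L))
    a <- array(NA_real_, dim = dims,
               dimnames = c(list(states[[v]]), lapply(pa, function(p) states[[p]])))
    body <- rows[[v]]$body
    if (!length(pa)) {
      nums <- sub(".*table([^;]*);.*", "\\1", body)
      a[] <- as.numeric(trimws(strsplit(nums, ",")[[1]]))
    } else {
      lm <- gregexpr("\\(([^)]*)\\)([^;]*);", body, perl = TRUE)
      for (ln in regmatches(body, lm)[[1]]) {
        idx <- trimws(strsplit(sub("\\(([^)]*)\\).*", "\\1", ln), ",")[[1]])
        p <- as.numeric(trimws(strsplit(sub("\\([^)]*\\)([^;]*);", "\\1", ln),
                                        ",")[[1]]))
        a <- do.call(`[<-`, c(list(a), list(seq_along(states[[v]])),
                              as.list(idx), list(value = p)))
      }
    }
    cpt[[v]] <- a
  }
  g <- bbn_dag(nodes, do.call(rbind, lapply(nodes, function(v)
    if (length(parents[[v]])) cbind(parents[[v]], v) else NULL)))
  structure(list(nodes = nodes, parents = g$parents, states = states,
                 cpt = cpt, pseudocount = NA_real_), class = "bbn")
}

#' Write a learned structure as an arc list
#'
#' One `source -> target` line per arc, for quick diffing of structures.
#' @param dag a `"bbn_dag"` or `"bbn"`.
#' @param path file path.
#' @export
write_arcs <- function(dag, path) {
  a <- arcs(dag)
  writeLines(if (nrow(a)) paste(a[, 1], "->", a[, 2]) else character(0), path)
  invisible(path)
}
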