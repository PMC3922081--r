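# Recursive-descent Newick parser retaining [&key=value] node comments.
# Returns a nested node list: children, label, length, comment.
parse_newick_nodes <- function(text) {
  s <- gsub("[\r\n\t ]", "", text)
  env <- new.env()
  env$pos <- 1L
  env$s <- s
  peek <- function() substr(env$s, env$pos, env$pos)
  advance <- function() env$pos <- env$pos + 1L
  fail <- function(msg) stop("newick parse error at position ", env$pos,
                             ": ", msg)
  read_comment <- function() {
    if (peek() != "[") return(NA_character_)
    end <- regexpr("]", substr(env$s, env$pos, nchar(env$s)), fixed = TRUE)
    if (end < 0L) fail("unterminated comment")
    out <- substr(env$s, env$pos + 1L, env$pos + end - 2L)
    env$pos <- env$pos + end
    out
  }
  read_label <- function() {
    m <- regexpr("^[^][(),:;]+", substr(env$s, env$pos, nchar(env$s)))
    if (m < 0L) return("")
    out <- substr(env$s, env$pos, env$pos + attr(m, "match.length") - 1L)
    env$pos <- env$pos + attr(m, "match.length")
    out
  }
  parse_node <- function() {
    node <- list(children = list(), label = "", length = NA_real_,
                 comment = NA_character_)
    if (peek() == "(") {
      advance()
      repeat {
        node$children[[length(node$children) + 1L]] <- parse_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    cm <- read_comment()
    node$label <- read_label()
    if (is.na(cm)) cm <- read_comment()
    node$comment <- cm
    if (peek() == ":") {
      advance()
      cm2 <- read_comment()              # branch comment (ignored)
      lab <- read_label()
      node$length <- suppressWarnings(as.numeric(lab))
      if (is.na(node$length)) fail("bad branch length")
      cm2 <- read_comment()
    }
    node
  }
  root <- parse_node()
  if (peek() != ";") fail("expected ';'")
  root
}

# nested node list -> phylo + per-node labels/comments
nodes_to_phylo <- function(root) {
  tips <- list(); internals <- list()
  count <- function(nd) {
    if (length(nd$children) == 0L) tips[[length(tips) + 1L]] <<- nd
    else { internals[[length(internals) + 1L]] <<- nd
           for (ch in nd$children) count(ch) }
  }
  count(root)
  nt <- length(tips); nn <- length(internals)
  if (nt < 2L) stop("tree must have at least 2 tips")
  edge <- matrix(0L, 0L, 2L); elen <- numeric(0)
  tip_label <- character(nt); node_label <- character(nn)
  comments <- character(nt + nn)
  it <- 0L; ii <- 0L
  assign_num <- function(nd) {
    if (length(nd$children) == 0L) {
      it <<- it + 1L
      tip_label[it] <<- nd$label
      comments[it] <<- nd$comment
      it
    } else {
      ii <<- ii + 1L
      me <- nt + ii
      node_label[ii] <<- nd$label
      comments[me] <<- nd$comment
      for (ch in nd$children) {
        chn <- assign_num(ch)
        edge <<- rbind(edge, c(me, chn))
        elen <<- c(elen, if (is.na(ch$length)) 0 else ch$length)
      }
      me
    }
  }
  assign_num(root)
  # edges were appended child-subtree-first; reorder parent rows first
  phy <- list(edge = edge, edge.length = elen, tip.label = tip_label,
              node.label = node_label, Nnode = nn)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  list(phylo = phy, comments = comments)
}

# "k=v,k2=v2" (with optional leading "&") -> named character vector
parse_comment_kv <- function(cm) {
  if (is.na(cm) || !nzchar(cm)) return(character(0))
  cm <- sub("^&", "", cm)
  parts <- strsplit(cm, ",(?=[^,=]+=)", perl = TRUE)[[1L]]
  kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
  out <- vapply(kv, function(x) if (length(x) == 2L) x[2L] else "",
                character(1L))
  names(out) <- vapply(kv, `[`, character(1L), 1L)
  out
}

#' Import a tree from Newick or NEXUS
#'
#' Parses internal-node support labels and `[&key=value]` node comments.
#' The support kind is auto-detected: values all at most 1 are tagged as
#' posterior probabilities, otherwise as bootstrap percentages.  NEXUS
#' translate tables are resolved.
#'
#' @param path file path (or a literal newick string ending in `;`).
#' @param format `"auto"`, `"newick"` or `"nexus"`.
#' @return `annotated_tree`; node metadata from comments appears as
#'   columns of `node_data`.
#' @export
import_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE),
                                      collapse = "\n") else path
  if (format == "auto")
    format <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE))
      "nexus" else "newick"
  translate <- NULL
  if (format == "nexus") {
    got <- nexus_extract_tree(txt)
    txt <- got$newick
    translate <- got$translate
  }
  txt <- sub("^\\[&[RU]\\]", "", trimws(txt))
  root <- parse_newick_nodes(txt)
  conv <- nodes_to_phylo(root)
  phy <- conv$phylo
  if (!is.null(translate)) {
    hit <- match(phy$tip.label, names(translate))
    phy$tip.label[!is.na(hit)] <- unname(translate[hit[!is.na(hit)]])
  }
  nt <- ape::Ntip(phy)
  sup_raw <- suppressWarnings(as.numeric(phy$node.label))
  support <- rep(NA_real_, phy$Nnode)
  kind <- "none"
  if (any(!is.na(sup_raw))) {
    ok <- sup_raw[!is.na(sup_raw)]
    kind <- if (all(ok <= 1)) "pp" else "bootstrap"
    support <- sup_raw
  }
  tr <- annotated_tree(phy, support = support, support_kind = kind)
  # node comments -> metadata columns
  kvs <- lapply(conv$comments, parse_comment_kv)
  keys <- unique(unlist(lapply(kvs, names)))
  for (key in keys) {
    tr$node_data[[key]] <- vapply(kvs, function(kv)
      if (key %in% names(kv)) kv[[key]] else NA_character_, character(1L))
  }
  tr
}

nexus_extract_tree <- function(txt) {
  lines <- strsplit(txt, "\n")[[1L]]
  low <- tolower(lines)
  translate <- NULL
  ti <- grep("^\\s*translate", low)
  if (length(ti)) {
    body <- character(0)
    j <- ti[1L]
    repeat {
      ln <- sub("^\\s*translate\\s*", "", lines[j],
                ignore.case = TRUE)
      body <- c(body, ln)
      if (grepl(";", lines[j])) break
      j <- j + 1L
      if (j > length(lines)) stop("unterminated translate table")
    }
    ent <- unlist(strsplit(paste(body, collapse = " "), ","))
    ent <- trimws(sub(";", "", ent))
    ent <- ent[nzchar(ent)]
    parts <- strsplit(ent, "\\s+")
    translate <- vapply(parts, `[`, character(1L), 2L)
    names(translate) <- vapply(parts, `[`, character(1L), 1L)
  }
  tl <- grep("^\\s*tree\\s", low)
  if (!length(tl)) stop("no tree statement found in NEXUS input")
  stmt <- lines[tl[1L]]
  k <- tl[1L]
  while (!grepl(";\\s*$", stmt) && k < length(lines)) {
    k <- k + 1L
    stmt <- paste0(stmt, lines[k])
  }
  nwk <- sub("^[^=]*=\\s*", "", stmt)
  list(newick = trimws(nwk), translate = translate)
}

# newick writer with optional node comments ([&...]) and labels
write_newick_string <- function(phy, node_labels = NULL,
                                comments = NULL) {
  nt <- ape::Ntip(phy)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  cm <- function(node) {
    if (is.null(comments) || is.na(comments[node]) ||
        !nzchar(comments[node])) "" else paste0("[&", comments[node], "]")
  }
  rec <- function(node, len) {
    body <- if (node <= nt) {
      paste0(phy$tip.label[node], cm(node))
    } else {
      ee <- children[[as.character(node)]]
      inner <- vapply(ee, function(e)
        rec(phy$edge[e, 2L], phy$edge.length[e]), character(1L))
      lab <- if (!is.null(node_labels)) node_labels[node - nt]
             else if (!is.null(phy$node.label))
               phy$node.label[node - nt] else ""
      if (is.na(lab)) lab <- ""
      paste0("(", paste(inner, collapse = ","), ")", lab, cm(node))
    }
    if (is.na(len)) body else paste0(body, ":", fmt_bl(len))
  }
  paste0(rec(nt + 1L, NA), ";")
}

#' Write an annotated tree as NEXUS with metadata comments
#'
#' Node metadata columns of `node_data` (other than `node` and `label`)
#' are serialized as `[&key=value]` comments; supports become internal
#' node labels.
#'
#' @param tree an `annotated_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotated_nexus <- function(tree, path) {
  phy <- as_phylo(tree)
  nt <- ape::Ntip(phy)
  nn <- phy$Nnode
  meta_cols <- setdiff(names(tree$node_data), c("node", "label"))
  comments <- rep(NA_character_, nt + nn)
  if (length(meta_cols)) {
    for (i in seq_len(nt + nn)) {
      row <- tree$node_data[tree$node_data$node == i, meta_cols,
                            drop = FALSE]
      if (nrow(row) == 0L) next
      vals <- unlist(row[1L, ])
      keep <- !is.na(vals) & nzchar(as.character(vals))
      if (any(keep))
        comments[i] <- paste0(meta_cols[keep], "=", vals[keep],
                              collapse = ",")
    }
  }
  labs <- if (!all(is.na(tree$support)))
    ifelse(is.na(tree$support), "", fmt_bl(tree$support)) else NULL
  nwk <- write_newick_string(phy, node_labels = labs,
                             comments = comments)
  con <- file(path, "w")
  on.exit(close(con))
  cat("#NEXUS\n\nbegin taxa;\n\tdimensions ntax=", nt, ";\n\ttaxlabels\n",
      paste0("\t\t", phy$tip.label, "\n", collapse = ""),
      "\t\t;\nend;\n\nbegin trees;\n\ttree annotated = ",
      if (tree$rooted) "[&R] " else "[&U] ", nwk, "\nend;\n",
      sep = "", file = con)
  invisible(path)
}

#' Export a tree as plain Newick
#'
#' @param tree `annotated_tree` or phylo.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  phy <- as_phylo(tree)
  labs <- if (inherits(tree, "annotated_tree") &&
              !all(is.na(tree$support)))
    ifelse(is.na(tree$support), "", fmt_bl(tree$support)) else NULL
  writeLines(write_newick_string(phy, node_labels = labs), path)
  invisible(path)
}
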