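#' Parse predicted secondary structures in dot-bracket notation
#'
#' Reads three-line records: region name, sequence, then the dot-bracket
#' structure followed by its minimum free energy in parentheses (kcal/mol),
#' the layout produced by RNAfold-style predictors. Co-folded records keep
#' their two strands in one record, separated in both the sequence and
#' structure lines by an ampersand (`&`) at the same index. Pseudoknot
#' symbols (`[`, `]`, `{`, `}`) are rejected; `U` and `T` are treated as
#' equivalent.
#'
#' @param path file path or character vector of lines.
#' @return A list of records, each a list with `name`, `sequence`,
#'   `dotbracket`, `mfe`, and `strands`: a list of per-strand data.frames
#'   with columns `index` and `pairing` (`paired`/`unpaired`).
#' @export
parse_structure_file <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L) {
    stop("expected 3-line records (name, sequence, structure)")
  }
  records <- vector("list", length(lines) / 3L)
  for (r in seq_along(records)) {
    name <- sub("^>\\s*", "", lines[3L * r - 2L])
    seq <- toupper(lines[3L * r - 1L])
    struct_line <- lines[3L * r]
    m <- regmatches(struct_line,
                    regexec("^(\\S+)\\s+\\((\\s*-?[0-9.]+)\\)$", struct_line))[[1]]
    if (length(m) != 3L) {
      stop("record '", name,
           "': structure line must end with the MFE in parentheses")
    }
    db <- m[2]
    mfe <- as.numeric(m[3])
    chars <- strsplit(db, "", fixed = TRUE)[[1]]
    if (any(chars %in% c("[", "]", "{", "}"))) {
      stop("record '", name, "': pseudoknot symbols are not supported")
    }
    if (!all(chars %in% c("(", ")", ".", "&"))) {
      stop("record '", name, "': invalid structure characters")
    }
    if (nchar(db) != nchar(seq)) {
      stop("record '", name, "': sequence and structure lengths differ")
    }
    seq_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    if (!all(seq_chars %in% c("A", "C", "G", "T", "U", "N", "&"))) {
      stop("record '", name, "': invalid sequence characters")
    }
    if (!identical(which(chars == "&"), which(seq_chars == "&"))) {
      stop("record '", name,
           "': '&' separators differ between sequence and structure")
    }
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0L) || depth[length(depth)] != 0L) {
      stop("record '", name, "': unbalanced brackets")
    }
    strand_id <- cumsum(chars == "&") + 1L
    keep <- chars != "&"
    strands <- lapply(split(chars[keep], strand_id[keep]), function(s) {
      data.frame(index = seq_along(s),
                 pairing = ifelse(s == ".", "unpaired", "paired"),
                 stringsAsFactors = FALSE)
    })
    records[[r]] <- list(name = name, sequence = seq, dotbracket = db,
                         mfe = mfe, strands = unname(strands))
  }
  records
}

#' Annotate every reference position with region and pairing
#'
#' Joins the region layout of the locus with per-region secondary structures
#' to label every position with its region (18S/ITS1/5.8S/ITS2/26S), region
#' class (subunit/spacer) and pairing state (paired stem / unpaired loop).
#' Structure records are matched to regions by name; a co-folded record
#' (e.g., `5.8S+26S`, two strands joined by `&`) is split at the separator
#' and its strands assigned to the named regions in order.
#'
#' @param regions region table (columns `region`, `start`, `end`, `class`).
#' @param structures list of records from [parse_structure_file()].
#' @return data.frame of class `site_annotation` with columns `position`,
#'   `region`, `region_class`, `pairing`, one row per reference position.
#' @export
annotate_sites <- function(regions, structures) {
  pairing_by_region <- list()
  for (rec in structures) {
    n_strands <- length(rec$strands)
    if (n_strands == 1L) {
      rnames <- rec$name
    } else {
      rnames <- strsplit(rec$name, "[+&/ ]+")[[1]]
      if (length(rnames) != n_strands) {
        stop("record '", rec$name, "' has ", n_strands,
             " strands but its name does not list that many regions")
      }
    }
    for (k in seq_len(n_strands)) {
      pairing_by_region[[rnames[k]]] <- rec$strands[[k]]$pairing
    }
  }
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions$region[i]
    len <- regions$end[i] - regions$start[i] + 1L
    pairing <- pairing_by_region[[rg]]
    if (is.null(pairing)) stop("no structure provided for region ", rg)
    if (length(pairing) != len) {
      stop("structure length (", length(pairing), ") does not match region ",
           rg, " (", len, " bp)")
    }
    out[[i]] <- data.frame(position = regions$start[i]:regions$end[i],
                           region = rg, region_class = regions$class[i],
                           pairing = pairing, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  ann <- ann[order(ann$position), ]
  rownames(ann) <- NULL
  if (!identical(ann$position, seq_len(nrow(ann)))) {
    stop("region intervals do not tile the reference")
  }
  class(ann) <- c("site_annotation", "data.frame")
  ann
}
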