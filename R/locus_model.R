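#' Construct a gene model for a locus with alternative 3' splice acceptors
#'
#' A gene model describes one locus: its reference sequence name and strand,
#' the exon intervals, the labelled splice sites, and the splice variants as
#' ordered exon chains. Coordinates are 0-based half-open on the forward
#' genome strand; strand-aware validation reads dinucleotides on the
#' transcribed strand. Site positions follow the intron-edge convention:
#' a donor's position is the first intronic base (the G of GT), an acceptor's
#' position is the last intronic base (the G of AG).
#'
#' @param reference Name of the reference sequence the coordinates refer to.
#' @param strand `"+"` or `"-"`.
#' @param exons A data frame with columns `name`, `start`, `end`
#'   (0-based half-open).
#' @param sites A data frame with columns `label`, `kind` (`"donor"` or
#'   `"acceptor"`) and `position`.
#' @param variants A named list mapping variant labels (e.g. `skip`, `X2`,
#'   `X3`, `X4`) to character vectors of exon names in transcription order.
#' @param sequence Optional reference sequence (a single string). Needed for
#'   [splice_transcript()], [translate_insert()] and site validation.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(reference, strand, exons, sites, variants,
                       sequence = NULL) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as_tibble(exons)
  sites <- as_tibble(sites)
  stopifnot(all(c("name", "start", "end") %in% names(exons)),
            all(c("label", "kind", "position") %in% names(sites)))
  if (any(exons$start < 0) || any(exons$start >= exons$end)) {
    abort("exon coordinates must satisfy 0 <= start < end")
  }
  if (anyDuplicated(sites$label)) {
    abort("splice-site labels must be unique within a gene model")
  }
  if (!all(sites$kind %in% c("donor", "acceptor"))) {
    abort("site kind must be 'donor' or 'acceptor'")
  }
  for (v in names(variants)) {
    chain <- variants[[v]]
    if (!all(chain %in% exons$name)) {
      abort(paste0("variant '", v, "' names unknown exons"))
    }
    iv <- exons[match(chain, exons$name), ]
    if (nrow(iv) > 1) {
      ord <- order(iv$start)
      if (is.unsorted(iv$start) && is.unsorted(rev(iv$start))) {
        abort(paste0("variant '", v, "' exon chain is not ordered"))
      }
      iv <- iv[ord, ]
      if (any(iv$start[-1] < iv$end[-nrow(iv)])) {
        abort(paste0("variant '", v, "' exon chain overlaps"))
      }
    }
  }
  structure(
    list(reference = reference, strand = strand, exons = exons,
         sites = sites, variants = variants, sequence = sequence),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$reference, " (", x$strand, ") ",
      nrow(x$exons), " exons, ", nrow(x$sites), " sites, ",
      length(x$variants), " variants: ",
      paste(names(x$variants), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Dinucleotide observed at a splice site, read on the transcribed strand.
site_dinucleotide <- function(site_kind, position, strand, sequence) {
  if (strand == "+") {
    if (site_kind == "donor") subseq0(sequence, position, position + 2L)
    else subseq0(sequence, position - 1L, position + 1L)
  } else {
    if (site_kind == "donor") revcomp(subseq0(sequence, position - 1L, position + 1L))
    else revcomp(subseq0(sequence, position, position + 2L))
  }
}

#' Validate a gene model against its reference sequence
#'
#' Checks that every declared donor reads GT and every acceptor reads AG on
#' the transcribed strand, and that all exons fall inside the reference.
#'
#' @param gm A [gene_model()].
#' @param sequence Reference sequence; defaults to `gm$sequence`.
#' @return `gm` invisibly; errors on violation.
#' @export
validate_gene_model <- function(gm, sequence = gm$sequence) {
  if (is.null(sequence)) abort("no reference sequence available for validation")
  n <- nchar(sequence)
  if (any(gm$exons$end > n)) abort("exon outside reference bounds")
  expected <- c(donor = "GT", acceptor = "AG")
  for (i in seq_len(nrow(gm$sites))) {
    s <- gm$sites[i, ]
    obs <- site_dinucleotide(s$kind, s$position, gm$strand, sequence)
    if (!identical(obs, unname(expected[s$kind]))) {
      abort(paste0("model-validation error: site '", s$label, "' (", s$kind,
                   ") reads '", obs, "' on the transcribed strand, expected ",
                   expected[s$kind]))
    }
  }
  invisible(gm)
}

#' Load a gene model from a JSON file
#'
#' The file format is a small JSON dialect with fields `reference`, `strand`,
#' `exons` (array of `{name, start, end}`), `sites` (array of
#' `{label, kind, position}`) and `variants` (object mapping variant label to
#' an array of exon names). Coordinates are 0-based half-open, forward
#' strand. If a FASTA is supplied, the reference is attached and the model
#' validated (donors must read GT, acceptors AG, on the transcribed strand).
#'
#' @param path Path to the gene-model JSON file.
#' @param fasta Optional path to a FASTA holding the reference sequence.
#' @return A validated [gene_model()].
#' @export
load_gene_model <- function(path, fasta = NULL) {
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("parse error in '", path, "': ",
                                     conditionMessage(e)))
  )
  for (f in c("reference", "strand", "exons", "sites", "variants")) {
    if (is.null(raw[[f]])) abort(paste0("gene-model file missing field '", f, "'"))
  }
  ex <- as_tibble(raw$exons)
  if (!is.numeric(ex$start) || !is.numeric(ex$end) ||
      any(is.na(ex$start)) || any(is.na(ex$end))) {
    bad <- which(is.na(suppressWarnings(as.numeric(ex$start))) |
                   is.na(suppressWarnings(as.numeric(ex$end))))
    abort(paste0("parse error: malformed coordinates in exon record(s) ",
                 paste(bad, collapse = ", ")))
  }
  seq <- NULL
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    if (!raw$reference %in% names(seqs)) {
      abort(paste0("reference '", raw$reference, "' not found in ", fasta))
    }
    seq <- unname(seqs[raw$reference])
  }
  variants <- lapply(raw$variants, as.character)
  gm <- gene_model(raw$reference, raw$strand, ex, as_tibble(raw$sites),
                   variants, sequence = seq)
  if (!is.null(seq)) validate_gene_model(gm)
  gm
}

#' Write a gene model to a JSON file
#'
#' @param gm A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(gm, path) {
  obj <- list(reference = gm$reference, strand = gm$strand,
              exons = gm$exons, sites = gm$sites, variants = gm$variants)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Intron-edge positions implied by an exon interval, per the site convention.
exon_donor_position <- function(exon, strand) {
  if (strand == "+") exon$end else exon$start - 1L
}
exon_acceptor_position <- function(exon, strand) {
  if (strand == "+") exon$start - 1L else exon$end
}

#' Enumerate the discriminating splice events of a gene model
#'
#' For each variant, the junction between its first two exons in
#' transcription order is the discriminating (donor, acceptor) pair: the one
#' read support for which identifies the variant. Variants whose chain has a
#' single exon contribute no event. The returned intron coordinates are
#' 0-based half-open on the forward strand (BED convention).
#'
#' @param gm A [gene_model()].
#' @return A tibble with columns `variant`, `donor`, `acceptor`, `chrom`,
#'   `intron_start`, `intron_end`, `strand`.
#' @export
event_catalog <- function(gm) {
  rows <- purrr::compact(purrr::map(names(gm$variants), function(v) {
    chain <- gm$variants[[v]]
    if (length(chain) < 2) return(NULL)
    iv <- gm$exons[match(chain, gm$exons$name), ]
    iv <- iv[order(iv$start, decreasing = (gm$strand == "-")), ]
    up <- iv[1, ]; down <- iv[2, ]
    dpos <- exon_donor_position(up, gm$strand)
    apos <- exon_acceptor_position(down, gm$strand)
    don <- gm$sites[gm$sites$kind == "donor" & gm$sites$position == dpos, ]
    acc <- gm$sites[gm$sites$kind == "acceptor" & gm$sites$position == apos, ]
    if (nrow(don) != 1 || nrow(acc) != 1) {
      abort(paste0("variant '", v, "': no labelled site at its first junction"))
    }
    if (gm$strand == "+") {
      is <- dpos; ie <- apos + 1L
    } else {
      is <- apos; ie <- dpos + 1L
    }
    tibble(variant = v, donor = don$label, acceptor = acc$label,
           chrom = gm$reference, intron_start = is, intron_end = ie,
           strand = gm$strand)
  }))
  cat <- dplyr::bind_rows(rows)
  key <- paste(cat$donor, cat$acceptor)
  if (anyDuplicated(key)) {
    abort(paste0("ambiguity error: variants ",
                 paste(cat$variant[key %in% key[duplicated(key)]], collapse = ", "),
                 " share the same (donor, acceptor) junction"))
  }
  cat
}

#' Splice a variant's transcript sequence from the reference
#'
#' Concatenates the variant's exon sequences in transcription order,
#' reverse-complementing for minus-strand models.
#'
#' @param gm A [gene_model()] with a reference sequence attached.
#' @param variant Variant label present in `gm$variants`.
#' @return The spliced transcript as a single string.
#' @export
splice_transcript <- function(gm, variant) {
  if (is.null(gm$sequence)) abort("gene model has no reference sequence")
  if (!variant %in% names(gm$variants)) {
    abort(paste0("unknown variant '", variant, "'"))
  }
  iv <- gm$exons[match(gm$variants[[variant]], gm$exons$name), ]
  if (any(iv$end > nchar(gm$sequence))) {
    abort("coordinate error: exon outside reference bounds")
  }
  iv <- iv[order(iv$start), ]
  fwd <- paste(purrr::map_chr(seq_len(nrow(iv)),
                              function(i) subseq0(gm$sequence, iv$start[i], iv$end[i])),
               collapse = "")
  if (gm$strand == "+") fwd else revcomp(fwd)
}

# Nucleotide insert of a variant relative to the skip variant: the transcribed
# sequence of the exons unique to the variant's chain.
variant_insert <- function(gm, variant, skip = "skip") {
  if (!skip %in% names(gm$variants)) abort("gene model has no skip variant")
  extra <- setdiff(gm$variants[[variant]], gm$variants[[skip]])
  if (length(extra) == 0) {
    abort(paste0("variant '", variant, "' has no insert relative to '", skip, "'"))
  }
  iv <- gm$exons[match(extra, gm$exons$name), ]
  iv <- iv[order(iv$start), ]
  fwd <- paste(purrr::map_chr(seq_len(nrow(iv)),
                              function(i) subseq0(gm$sequence, iv$start[i], iv$end[i])),
               collapse = "")
  if (gm$strand == "+") fwd else revcomp(fwd)
}

#' Translate the peptide insert encoded by a splice variant
#'
#' Extracts the nucleotides a variant adds relative to the exon-skipping
#' transcript and translates them with the standard genetic code. An in-frame
#' stop truncates the peptide and is flagged.
#'
#' @param gm A [gene_model()] with reference sequence.
#' @param variant Variant label (must carry an insert, i.e. not the skip
#'   variant).
#' @param frame_offset Reading-frame offset (0, 1 or 2) relative to the
#'   insert start. Default 0.
#' @return A one-row tibble: `variant`, `insert_nt` (nucleotide length of the
#'   raw insert), `peptide`, `n_residues`, `truncated`.
#' @export
translate_insert <- function(gm, variant, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  ins <- variant_insert(gm, variant)
  coding <- substr(ins, frame_offset + 1L, nchar(ins))
  if (nchar(coding) < 3) abort("insert shorter than one codon in this frame")
  coding <- substr(coding, 1L, 3L * (nchar(coding) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(coding)))
  truncated <- FALSE
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    aa <- substr(aa, 1L, stop_at - 1L)
    truncated <- TRUE
  }
  tibble(variant = variant, insert_nt = nchar(ins), peptide = aa,
         n_residues = nchar(aa), truncated = truncated)
}
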