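#' Construct a Selection
#'
#' A `Selection` is an ordered list of `(chain, residue number, optional
#' atom-name filter)` rows. Resolution against a [topology()] is
#' deterministic and order-preserving: atoms are returned row by row, in
#' topology order within a row.
#'
#' @param resno Integer vector of author residue numbers.
#' @param chain Chain id(s), recycled; `NA` matches any chain.
#' @param name Atom-name filter(s), recycled; `NA` matches any atom name.
#' @param label Optional selection name.
#' @return Object of class `Selection`.
#' @export
selection <- function(resno, chain = NA, name = NA, label = NULL) {
  tab <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                    name = as.character(name), stringsAsFactors = FALSE)
  structure(list(label = label %||% "selection", table = tab),
            class = "Selection")
}

#' Cα selection over residue numbers
#' @inheritParams selection
#' @return A [selection()] restricted to `CA` atoms.
#' @export
ca_selection <- function(resno, chain = NA, label = NULL) {
  selection(resno, chain = chain, name = "CA", label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a Selection to atom indices
#'
#' @param top A [topology()].
#' @param sel A [selection()], or an integer vector of atom indices (returned
#'   unchanged, for convenience).
#' @return Integer atom indices; errors if the selection matches no atom.
#' @export
resolve_selection <- function(top, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  if (!inherits(sel, "Selection")) {
    stop(mp_error("selection", "not a Selection object"))
  }
  at <- top$atoms
  idx <- unlist(lapply(seq_len(nrow(sel$table)), function(i) {
    r <- sel$table[i, ]
    keep <- at$resno == r$resno
    if (!is.na(r$chain)) keep <- keep & at$chain == r$chain
    if (!is.na(r$name)) keep <- keep & at$name == r$name
    which(keep)
  }), use.names = FALSE)
  if (length(idx) == 0) {
    stop(mp_error("selection", "selection '%s' resolves to no atom",
                  sel$label))
  }
  idx
}

# expand "a-b" range strings / scalars from the preset YAML into a vector
parse_resno_spec <- function(x) {
  unlist(lapply(x, function(el) {
    if (is.numeric(el)) return(as.integer(el))
    el <- trimws(as.character(el))
    if (grepl("^\\d+\\s*-\\s*\\d+$", el)) {
      ab <- as.integer(strsplit(el, "\\s*-\\s*")[[1]])
      return(seq.int(ab[1], ab[2]))
    }
    as.integer(el)
  }), use.names = FALSE)
}

#' Load named selection presets
#'
#' Presets hold the residue sets the transition probes operate on (IC half of
#' TM5, core-fit exclusions, PCA core, Na2 site, IC exit pathway, gate
#' residue pairs, hinge residue) in the transporter's author numbering.
#' `"hdat"` and `"hsert"` ship with the package; a path loads a custom YAML
#' file with the same keys.
#'
#' @param preset `"hdat"`, `"hsert"`, or a path to a YAML preset file.
#' @return Object of class `SelectionPresets`: list of integer residue
#'   vectors (`tm5_ic_half`, `tm5_full`, `core_fit_exclusions`, `pca_core`,
#'   `na2_site`, `ic_exit_path`, `t_probe`), the hinge residue `tm5_hinge`,
#'   and a `gates` data.frame (`label`, `a`, `b`, `type`, `group`).
#' @export
load_selection_presets <- function(preset = "hdat") {
  path <- if (file.exists(preset)) preset else
    system.file("extdata", paste0("presets_", preset, ".yaml"),
                package = "memprobe")
  if (!nzchar(path) || !file.exists(path)) {
    stop(mp_error("config", "unknown preset '%s'", preset))
  }
  y <- yaml::read_yaml(path)
  gates <- do.call(rbind, lapply(c("ec_gates", "ic_gates", "extra_pairs"),
    function(g) {
      if (is.null(y[[g]])) return(NULL)
      do.call(rbind, lapply(y[[g]], function(p) {
        data.frame(label = p$label, a = as.integer(p$a), b = as.integer(p$b),
                   type = p$type, group = sub("s$|_pairs$", "", g),
                   stringsAsFactors = FALSE)
      }))
    }))
  out <- list(
    numbering = y$numbering %||% "custom",
    tm5_ic_half = parse_resno_spec(y$tm5_ic_half),
    tm5_full = parse_resno_spec(y$tm5_full),
    core_fit_exclusions = parse_resno_spec(y$core_fit_exclusions),
    pca_core = parse_resno_spec(y$pca_core),
    na2_site = parse_resno_spec(y$na2_site),
    ic_exit_path = parse_resno_spec(y$ic_exit_path),
    t_probe = parse_resno_spec(y$t_probe),
    tm5_hinge = as.integer(y$tm5_hinge),
    gates = gates)
  structure(out, class = "SelectionPresets")
}

#' @export
print.SelectionPresets <- function(x, ...) {
  cat(sprintf("SelectionPresets (%s numbering)\n", x$numbering))
  for (k in c("tm5_ic_half", "tm5_full", "na2_site", "ic_exit_path",
              "t_probe")) {
    cat(sprintf("  %-20s %s\n", k, paste(range(x[[k]]), collapse = "-")))
  }
  cat(sprintf("  %-20s %d\n", "tm5_hinge", x$tm5_hinge))
  cat(sprintf("  %d gate pair(s)\n", nrow(x$gates)))
  invisible(x)
}
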