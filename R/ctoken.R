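## Lexical analysis of ISO C90/C99 source. Purely lexical, per file: no
## macro expansion, no #include following, no trigraphs. The measured
## quantity is the written token stream.

.C_KEYWORDS <- c(
  "auto", "break", "case", "char", "const", "continue", "default", "do",
  "double", "else", "enum", "extern", "float", "for", "goto", "if",
  "inline", "int", "long", "register", "restrict", "return", "short",
  "signed", "sizeof", "static", "struct", "switch", "typedef", "union",
  "unsigned", "void", "volatile", "while")

.opsMulti <- c(">>=", "<<=", "...", "->", "++", "--", "<<", ">>", "<=",
               ">=", "==", "!=", "&&", "||", "+=", "-=", "*=", "/=", "%=",
               "&=", "^=", "|=", "##")
.opsSingle <- c("[", "]", "{", "}", "(", ")", "<", ">", "=", "+", "-", "*",
                "/", "%", "&", "^", "|", "!", "~", "?", ":", ";", ",", ".")

.escRe <- function(x) gsub("([][{}()<>=+*/%&^|!~?:;,.#\\\\-])",
                           "\\\\\\1", x)

## single alternation implementing maximal munch: alternatives are tried
## left to right, longer operators listed before their prefixes
.tokPattern <- function() {
  paste0(
    "(?s)",
    "/\\*.*?\\*/",
    "|//[^\\n]*",
    "|\"(?:\\\\.|[^\"\\\\\\n])*\"",
    "|'(?:\\\\.|[^'\\\\\\n])+'",
    "|#[ \\t]*[A-Za-z_]+",
    "|0[xX][0-9A-Fa-f]+[uUlL]*",
    "|(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?[uUlLfF]*",
    "|[A-Za-z_][A-Za-z0-9_]*",
    "|", paste(c(.escRe(.opsMulti), .escRe(.opsSingle)), collapse = "|"),
    "|[ \\t\\r\\n\\f\\v]+"
  )
}

#' Tokenize ISO C90/C99 source text
#'
#' Maximal-munch lexing of a single translation unit: comments are removed,
#' whitespace is discarded, and every surviving character belongs to exactly
#' one token. Preprocessor directives are tokenized (the `#name` directive
#' as one token of class `preprocessor`, its payload as ordinary tokens).
#' Token identity is the exact spelling, so `0` and `0x0` are distinct and
#' string literals are distinct by their full spelling.
#'
#' @param source_text Character scalar of C source, or `NULL` if `file` is
#'   given.
#' @param file Optional path to a `.c`/`.h` file to read.
#' @return Data frame with columns `text`, `class` (one of `keyword`,
#'   `identifier`, `numeric-constant`, `char-constant`, `string-literal`,
#'   `operator-punctuator`, `preprocessor`) and `line`.
#'   Unterminated strings, character constants or comments raise an error
#'   naming the line.
#' @examples
#' tokenizeC("int main(void){return 0;}")$text
#' @export
tokenizeC <- function(source_text = NULL, file = NULL) {
  if (is.null(source_text)) {
    if (is.null(file)) stop("supply 'source_text' or 'file'")
    source_text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  stopifnot(is.character(source_text), length(source_text) == 1L)
  if (!nzchar(source_text))
    return(data.frame(text = character(0), class = character(0),
                      line = integer(0), stringsAsFactors = FALSE))
  m <- gregexpr(.tokPattern(), source_text, perl = TRUE)[[1L]]
  st <- as.integer(m)
  if (st[1L] == -1L) st <- integer(0)
  len <- attr(m, "match.length")
  end <- st + len - 1L
  ## coverage check: any gap is a lexical error
  gapAt <- NA_integer_
  if (length(st) == 0L) {
    gapAt <- 1L
  } else {
    if (st[1L] != 1L) gapAt <- 1L
    holes <- which(st[-1L] != end[-length(end)] + 1L)
    if (length(holes)) gapAt <- min(gapAt, end[holes[1L]] + 1L, na.rm = TRUE)
    if (is.na(gapAt) && end[length(end)] != nchar(source_text))
      gapAt <- end[length(end)] + 1L
  }
  nlPos <- gregexpr("\n", source_text, fixed = TRUE)[[1L]]
  lineOf <- function(pos) {
    if (nlPos[1L] == -1L) return(rep(1L, length(pos)))
    findInterval(pos, nlPos) + 1L
  }
  if (!is.na(gapAt)) {
    nxt <- substr(source_text, gapAt, gapAt + 1L)
    what <- if (substr(nxt, 1L, 1L) == "\"") "unterminated string literal"
            else if (substr(nxt, 1L, 1L) == "'") "unterminated character constant"
            else if (nxt == "/*") "unterminated comment"
            else sprintf("unexpected character '%s'", substr(nxt, 1L, 1L))
    stop(sprintf("lexical error at line %d: %s", lineOf(gapAt), what))
  }
  txt <- substring(source_text, st, end)
  first <- substr(txt, 1L, 1L)
  isWs <- first %in% c(" ", "\t", "\r", "\n", "\f", "\v")
  isCm <- startsWith(txt, "/*") | startsWith(txt, "//")
  keep <- !isWs & !isCm
  txt <- txt[keep]; first <- first[keep]; stK <- st[keep]
  ## a literal "/*" surviving comment removal can only be an unterminated
  ## comment: the lexer would otherwise have consumed it as one
  if (length(txt) > 1L) {
    adj <- which(txt[-length(txt)] == "/" &
                 stK[-1L] == stK[-length(stK)] + 1L &
                 substr(txt[-1L], 1L, 1L) == "*")
    if (length(adj))
      stop(sprintf("lexical error at line %d: unterminated comment",
                   lineOf(stK[adj[1L]])))
  }
  cls <- rep("operator-punctuator", length(txt))
  cls[first == "#"] <- "preprocessor"
  cls[txt == "##"] <- "operator-punctuator"
  cls[first == "\""] <- "string-literal"
  cls[first == "'"] <- "char-constant"
  isNum <- grepl("^[0-9.]", txt) & first != "."
  cls[isNum | grepl("^\\.[0-9]", txt)] <- "numeric-constant"
  isIdent <- grepl("^[A-Za-z_]", txt)
  cls[isIdent] <- ifelse(txt[isIdent] %in% .C_KEYWORDS, "keyword",
                         "identifier")
  data.frame(text = txt, class = cls, line = lineOf(stK),
             stringsAsFactors = FALSE)
}

#' Extract top-level function definitions from a token stream
#'
#' Scans for `identifier ( ... ) {` at brace depth zero; the span runs from
#' the start of the declaration-specifier run (the unbroken run of
#' keywords, identifiers and `*` preceding the function name) through the
#' matching closing brace. Declarations, struct definitions and K&R-style
#' definitions yield no span. Any preprocessor tokens lying inside a span
#' count towards its token length.
#'
#' @param tokens A token data frame from [tokenizeC()].
#' @return Data frame with columns `name`, `first`, `last` (token indices)
#'   and `token_length`. Unbalanced braces at end of input raise an error
#'   naming the line of the last open brace.
#' @examples
#' extractFunctions(tokenizeC("int main(void){return 0;}"))
#' @export
extractFunctions <- function(tokens) {
  txt <- tokens$text; cls <- tokens$class; n <- length(txt)
  spans <- list()
  depth <- 0L; i <- 1L
  lastOpen <- NA_integer_
  while (i <= n) {
    tk <- txt[i]
    if (tk == "{") { depth <- depth + 1L; lastOpen <- i; i <- i + 1L; next }
    if (tk == "}") { depth <- depth - 1L; i <- i + 1L; next }
    if (depth == 0L && cls[i] == "identifier" && i + 1L <= n &&
        txt[i + 1L] == "(") {
      # find matching close paren
      j <- i + 1L; pd <- 0L
      while (j <= n) {
        if (txt[j] == "(") pd <- pd + 1L
        if (txt[j] == ")") { pd <- pd - 1L; if (pd == 0L) break }
        j <- j + 1L
      }
      if (j <= n && j + 1L <= n && txt[j + 1L] == "{") {
        # walk back over the declaration-specifier run
        first <- i
        k <- i - 1L
        while (k >= 1L &&
               (cls[k] %in% c("keyword", "identifier") || txt[k] == "*")) {
          first <- k; k <- k - 1L
        }
        # walk forward to the matching closing brace
        m <- j + 1L; bd <- 0L
        while (m <= n) {
          if (txt[m] == "{") { bd <- bd + 1L; lastOpen <- m }
          if (txt[m] == "}") { bd <- bd - 1L; if (bd == 0L) break }
          m <- m + 1L
        }
        if (m > n)
          stop(sprintf("unbalanced braces at end of input (last '{' at line %d)",
                       tokens$line[lastOpen]))
        spans[[length(spans) + 1L]] <-
          data.frame(name = txt[i], first = first, last = m,
                     token_length = m - first + 1L,
                     stringsAsFactors = FALSE)
        i <- m + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (depth > 0L)
    stop(sprintf("unbalanced braces at end of input (last '{' at line %d)",
                 tokens$line[lastOpen]))
  if (length(spans) == 0L)
    return(data.frame(name = character(0), first = integer(0),
                      last = integer(0), token_length = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, spans)
}

#' Corpus-wide token frequencies
#'
#' Counts of distinct token spellings across a corpus. Input may be a token
#' data frame, a list of them, or a directory path (every `*.c` / `*.h`
#' file under it is tokenized). The result is invariant under permutation
#' of the files. Ranks derived from these counts break ties by
#' lexicographic token text, so rank plots are deterministic.
#'
#' @param x Token data frame, list of token data frames, or directory path.
#' @param pattern File glob used when `x` is a directory (default
#'   `\\.(c|h)$`).
#' @return Named integer vector of counts, sorted by decreasing count with
#'   lexicographic tie-break.
#' @export
tokenFrequencies <- function(x, pattern = "\\.(c|h)$") {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = pattern, recursive = TRUE,
                             full.names = TRUE))
    x <- lapply(files, function(f) tokenizeC(file = f))
  }
  if (is.data.frame(x)) x <- list(x)
  texts <- unlist(lapply(x, `[[`, "text"), use.names = FALSE)
  if (length(texts) == 0L) return(integer(0))
  tab <- table(texts)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts), method = "radix")]
}

#' Render a token stream back to text
#'
#' Concatenates token texts with single spaces. Because lexing is maximal
#' munch, re-tokenizing the rendering reproduces the identical token
#' sequence (the round-trip identity used in the tests).
#'
#' @param tokens A token data frame from [tokenizeC()].
#' @return Character scalar.
#' @export
renderTokens <- function(tokens) {
  paste(tokens$text, collapse = " ")
}
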