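test_that("hand-lexed snippets reproduce token for token", {
  tk <- tokenizeC("int main(void){return 0;}")
  expect_equal(tk$text, c("int", "main", "(", "void", ")", "{",
                          "return", "0", ";", "}"))
  expect_equal(tk$class[1], "keyword")
  expect_equal(tk$class[2], "identifier")
  expect_equal(tk$class[8], "numeric-constant")
  expect_equal(tokenizeC("/* note */ x;")$text, c("x", ";"))
  # maximal munch
  expect_equal(tokenizeC("a+++b")$text, c("a", "++", "+", "b"))
  expect_equal(tokenizeC("a>>=b")$text, c("a", ">>=", "b"))
})

test_that("comments, strings, chars and preprocessor lines lex correctly", {
  tk <- tokenizeC("#include <stdio.h>\nchar *s = \"a b /* x */\";\n")
  expect_equal(tk$text[1], "#include")
  expect_equal(tk$class[1], "preprocessor")
  expect_true("\"a b /* x */\"" %in% tk$text)
  expect_equal(tk$class[tk$text == "\"a b /* x */\""], "string-literal")
  tk2 <- tokenizeC("c = 'x'; d = '\\n';")
  expect_equal(sum(tk2$class == "char-constant"), 2L)
  # line numbers
  tk3 <- tokenizeC("int a;\nint b;\n// gone\nint c;")
  expect_equal(tk3$line[tk3$text == "c"], 4L)
  # token identity is exact spelling: 0 and 0x0 are distinct
  tk4 <- tokenizeC("x = 0; y = 0x0;")
  expect_true(all(c("0", "0x0") %in% tk4$text))
})

test_that("lexical errors carry line numbers", {
  expect_error(tokenizeC("int a;\nchar *s = \"oops;\n"),
               "line 2.*unterminated string")
  expect_error(tokenizeC("/* never closed\nint a;"),
               "line 1.*unterminated comment")
  expect_error(tokenizeC("int a @ b;"), "unexpected character '@'")
})

test_that("every C89 keyword classifies as keyword; identifiers are case-sensitive", {
  kw <- c("auto", "break", "case", "char", "const", "continue", "default",
          "do", "double", "else", "enum", "extern", "float", "for", "goto",
          "if", "int", "long", "register", "return", "short", "signed",
          "sizeof", "static", "struct", "switch", "typedef", "union",
          "unsigned", "void", "volatile", "while")
  tk <- tokenizeC(paste(kw, collapse = " "))
  expect_true(all(tk$class == "keyword"))
  fr <- tokenFrequencies(tokenizeC("Foo foo FOO Foo"))
  expect_equal(fr[["Foo"]], 2L)
  expect_equal(fr[["foo"]], 1L)
})

test_that("function spans are recognised at brace depth zero", {
  tk <- tokenizeC("int main(void){return 0;}")
  sp <- extractFunctions(tk)
  expect_equal(sp$name, "main")
  expect_equal(sp$token_length, 10L)
  # declarations and struct definitions yield no span
  none <- extractFunctions(tokenizeC(
    "int x; extern int f(int); struct s { int a; };"))
  expect_equal(nrow(none), 0L)
  # nested blocks stay inside one span
  src <- "static long g(int n) { if (n) { while (n) { n--; } } return n; }"
  sp2 <- extractFunctions(tokenizeC(src))
  expect_equal(nrow(sp2), 1L)
  expect_equal(sp2$name, "g")
  expect_equal(sp2$last, length(tokenizeC(src)$text))
  expect_error(extractFunctions(tokenizeC("int f(void) { {")),
               "unbalanced braces")
})

test_that("per-function token lengths never exceed the file total", {
  src <- paste("int a(void){return 1;}",
               "int x;",
               "int b(int k){ k += 2; return k; }", sep = "\n")
  tk <- tokenizeC(src)
  sp <- extractFunctions(tk)
  expect_equal(nrow(sp), 2L)
  expect_lte(sum(sp$token_length), nrow(tk))
})

test_that("token frequencies are exact, order-invariant counts", {
  a <- tokenizeC("x x y")
  expect_equal(unname(tokenFrequencies(a)[c("x", "y")]), c(2L, 1L))
  f1 <- tokenizeC("alpha beta")
  f2 <- tokenizeC("beta gamma beta")
  expect_identical(tokenFrequencies(list(f1, f2)),
                   tokenFrequencies(list(f2, f1)))
  # deterministic rank tie-break is lexicographic
  fr <- tokenFrequencies(tokenizeC("b a c"))
  expect_equal(names(fr), c("a", "b", "c"))
})

test_that("render and re-tokenize is the identity on token streams", {
  snippets <- c(
    "int main(void){return 0;}",
    "a+++b",
    "#define N 10\nint v[N];",
    "x = y >>= 3; s = \"lit \\\" str\"; c = 'q';",
    "for (i = 0; i < n; ++i) total += w[i] * 2.5e-3;")
  for (src in snippets) {
    tk <- tokenizeC(src)
    back <- tokenizeC(renderTokens(tk))
    expect_identical(back$text, tk$text)
    expect_identical(back$class, tk$class)
  }
})
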