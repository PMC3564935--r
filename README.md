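# meshopr

Term over-representation profiles for biomedical entities.

Literature databases annotate every article with descriptors from a
controlled vocabulary organized as a hierarchy (MeSH being the canonical
example).  Given such a vocabulary, an annotated article corpus, and the
set of articles linked to an entity — a gene, a disease, a chemical, a
research topic — `meshopr` computes the entity's **over-representation
profile**: a vector of (term, p-value) pairs, one per vocabulary term
occurring in the entity's literature, quantifying how surprisingly often
each term is attached to those articles.

It is aimed at literature-mining and annotation work: summarizing what is
known about an entity, comparing entities by what is written about them,
tracking how a field's focus shifts over time, and rendering profiles as
word clouds.

## The statistic

Annotations are first closed upward through the hierarchy: an article
tagged with a term counts as tagged with every ancestor of that term
(curators assign only the most specific descriptors).  For a foreground of
*n* articles inside a background of *N* annotated articles, a term present
in *a* foreground articles and *k* background articles gives the 2x2 table
(a, n−a, k−a, N−n−(k−a)), scored by the one-sided Fisher's exact test

> p = P(X ≥ a),  X ~ Hypergeometric(N, k, n),

the probability that an equally sized random article set would carry the
term at least as prevalently.  The background is either *universal* (all
annotated articles) or *class-specific* (articles addressing any member of
the entity's class), the latter absorbing enrichment generic to the class.

On top of the core profile the package provides specificity filtering
(keep only the most specific significant terms — an antichain of the
hierarchy), query-term exclusion, temporal slicing (the 50 most recent
articles up to a year), Euclidean profile distances with complete-linkage
clustering, Bonferroni correction, word-cloud export, and a synthetic
corpus generator with planted signal used for validation.

## Worked example

A synthetic corpus with one entity whose articles over-use a planted leaf
term (probability 0.5 vs a background rate of 0.05):

```r
library(meshopr)
vocab <- make_toy_vocab(3, 3)                         # 39-term toy tree
syn   <- generate_corpus(recovery_spec(seed = 1), vocab)
m     <- meshop(syn$bibliographies[["entity1"]], syn$corpus, vocab)
print(m, n = 5)
#> Term over-representation profile for 'entity1'
#>   foreground: 24 articles (6 dropped)
#>   background: universal ( 408 articles )
#>   terms scored: 33
#>   top terms:
#>             term  a   k        p
#>  Toy term N1_1_1 12  24 1.37e-10
#>    Toy term N1_1 14  83 2.65e-05
#>      Toy term N1 20 213 1.18e-03
#>  Toy term N3_2_1  4  32 1.08e-01
#>  Toy term N1_1_2  4  35 1.40e-01
```

The planted leaf `N1_1_1` tops the profile (12 of 24 foreground articles
carry it versus 24 of 408 in the background, p ≈ 1.4e-10), followed by its
ancestors `N1_1` and `N1`, which are enriched only because the closure of
the planted leaf implies them.  Specificity filtering removes such implied
generalities:

```r
f <- filter_most_specific(m, vocab, alpha = 0.05)
as.data.frame(f)
#>   term_id       term_name  a fg_size  k bg_size     p_value
#> 1  N1_1_1 Toy term N1_1_1 12      24 24     408 1.37319e-10

write_tagcloud(to_cloud(f), stdout())
#> Toy term N1_1_1:9.862
```

The cloud line is the term's name with weight −log10(p) (capped at 30),
the font-size input of tag-cloud renderers.

The same workflows are scriptable from a shell via the installed
`scripts/meshop` entry point (subcommands `profile`, `filter`, `cloud`,
`compare`, `temporal`, `synth`), which reads the plain TSV dialects
documented in the function reference: a vocabulary table or descriptor
ASCII file, an `article_id / year / terms` annotation table, gene2pubmed
or GeneRIF link files, and plain PMID lists.

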