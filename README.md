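# rfftscan

Automated scoring of scanned **Ruff Figural Fluency Test (RFFT)**
protocols. The RFFT asks a respondent to draw, in each of five one-minute
parts, as many unique dot-connecting designs as possible on a sheet of 35
five-dot patterns; repetitions within a part are perseverative errors.
Human scoring is slow and rater-dependent, so this package scores color
scans of the sheets by automated pattern recognition, and provides the
agreement statistics used to compare two assessments of the same
protocols.

## What it computes

A five-dot pattern admits C(5,2) = 10 straight connections; a design is a
non-empty subset of them, so there are 2^10 − 1 = 1023 possible designs.
Each cell is encoded as a 10-bit **design ID** (bit *k* set iff canonical
connection *k* is drawn). Recognition runs five tasks per cell:

1. identify the **active dots** (touched by red ink);
2. enumerate the **candidate connections** between active dots;
3. designate every red pixel to the nearest candidate within a corridor;
4. check **line compatibility** (projection coverage ≥ 0.75 of the
   segment, largest gap ≤ 0.20);
5. reject **false positives** (collinear subsumption by an active
   interior dot).

Strokes crossing *through* dots ("violations") are detected by overshoot
past the dot centers and excluded from the design. Scores per part and
protocol: unique designs, perseverative errors, violations.

Agreement between two assessments: **ICC(A,1)** (two-way,
absolute-agreement, single measures), **Lin's concordance correlation**,
and **Bland–Altman 95% limits of agreement** (mean ± 1.96 SD of the
differences), plus the reconciliation rule for a third rater (required
when two raters differ by > 2 points in a part or > 4 in total; the most
concordant pair is averaged).

Because clinical scans cannot ship with the package, a synthetic renderer
draws protocol pages (black dots, diamond/line distractors, red strokes
with hand-drawing noise and a violation mode) from a known script and the
pipeline is validated against that ground truth.

## Worked example

```r
library(rfftscan)

lay    <- defaultBoardLayout(150)                       # 150 dpi geometry
script <- randomScript(18, 0.10, seed = 42, violationRate = 0.02)
pages  <- renderProtocol(script, lay, strokeNoiseModel(dpi = 150, seed = 42L))
score  <- scoreRendered(pages)
score
#> ProtocolScore
#>  part attempted uniqueDesigns perseverativeErrors violations unscorable
#>     1        17            17                   0          6          0
#>     2        15            14                   1         14          0
#>     3        18            16                   2          0          0
#>     4        18            17                   1          0          0
#>     5        18            18                   0          0          0
#>   total: 82 unique, 4 perseverative, 20 violations
```

Each row is one part: `attempted` cells carried a recognizable design,
split into first occurrences (`uniqueDesigns`) and repeats
(`perseverativeErrors`); `violations` counts strokes drawn through the
dots (those cells are excluded from the design tallies). Scoring the
script directly (`scoreScript(script)`) gives the same totals — the
pipeline recovered the ground truth exactly.

Bland–Altman limits from published summary statistics:

```r
limitsFromSummary(-1.42, 2.78)
#> lower upper
#> -6.87  4.03
```

To score real scans, put the five pages of each protocol in a directory as
`<id>_part1.png` … `<id>_part5.png` and run `scoreProtocolDir()` (or the
`inst/scripts/rfftscan` command-line wrapper with `score`, `agree` and
`simulate` subcommands). The default board layout is a documented
approximation of the licensed RFFT sheets; measure and supply your own
layout YAML (`readBoardLayout()`) for production use.

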