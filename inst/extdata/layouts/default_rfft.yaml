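# Default synthetic RFFT board layout.
#
# Approximates the published description of the test sheets: an 8.5 x 11"
# page with 35 five-dot patterns in seven rows and five columns; a regular
# pentagon in parts 1-3 with diamond distractors in part 2 and line
# distractors in part 3; parts 4-5 use the pentagon rotated 180 degrees
# (the true variant arrangement is licensed artwork and is not reproduced
# here). Coordinates of dots and distractors are normalized to the unit
# square (origin top-left, x rightward, y downward) and are mapped onto a
# centered square occupying dot_square_frac of the smaller cell dimension.
name: default_rfft_synthetic
dpi: 300
page_width_in: 8.5
page_height_in: 11.0
grid:
  n_rows: 7
  n_cols: 5
  margin_left_in: 0.5
  margin_right_in: 0.5
  margin_top_in: 1.0
  margin_bottom_in: 0.5
dot_radius_in: 0.028
dot_square_frac: 0.80
parts:
  - part: 1
    distractor_kind: none
    dots:
      - [0.500000, 0.050000]
      - [0.927975, 0.360942]
      - [0.764503, 0.864058]
      - [0.235497, 0.864058]
      - [0.072025, 0.360942]
  - part: 2
    distractor_kind: diamonds
    dots:
      - [0.500000, 0.050000]
      - [0.927975, 0.360942]
      - [0.764503, 0.864058]
      - [0.235497, 0.864058]
      - [0.072025, 0.360942]
    distractor_size: 0.016
    distractors:
      - [0.629313, 0.322016]
      - [0.709232, 0.567984]
      - [0.500000, 0.720000]
      - [0.290768, 0.567984]
      - [0.370687, 0.322016]
  - part: 3
    distractor_kind: lines
    dots:
      - [0.500000, 0.050000]
      - [0.927975, 0.360942]
      - [0.764503, 0.864058]
      - [0.235497, 0.864058]
      - [0.072025, 0.360942]
    distractor_size: 0.060
    distractor_angles: [0.628319, 1.884956, 3.141593, 4.398230, 5.654867]
    distractors:
      - [0.629313, 0.322016]
      - [0.709232, 0.567984]
      - [0.500000, 0.720000]
      - [0.290768, 0.567984]
      - [0.370687, 0.322016]
  - part: 4
    distractor_kind: none
    dots:
      - [0.500000, 0.950000]
      - [0.072025, 0.639058]
      - [0.235497, 0.135942]
      - [0.764503, 0.135942]
      - [0.927975, 0.639058]
  - part: 5
    distractor_kind: none
    dots:
      - [0.500000, 0.950000]
      - [0.072025, 0.639058]
      - [0.235497, 0.135942]
      - [0.764503, 0.135942]
      - [0.927975, 0.639058]
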