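{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "migrec model configuration",
  "description": "A migration-recombination model: site alphabets, deme set, backward (or forward + sizes) migration matrix, recombination distribution over partitions of the site set, optional per-deme initial type distributions (flat tables in lexicographic order, site 1 most significant), and an optional continuous-time block (rates + generator).",
  "type": "object",
  "required": ["n", "alphabets", "demes"],
  "properties": {
    "n": { "type": "integer", "minimum": 1, "description": "number of sites" },
    "alphabets": {
      "type": "array",
      "description": "one array of letter names per site",
      "items": { "type": "array", "items": { "type": "string" }, "minItems": 1 }
    },
    "demes": {
      "type": "array", "items": { "type": "string" }, "minItems": 1
    },
    "migration": {
      "type": "object",
      "description": "either a backward matrix, or a forward matrix plus deme sizes from which the backward matrix is derived",
      "properties": {
        "backward": { "$ref": "#/$defs/rowStochasticMatrix" },
        "forward": { "$ref": "#/$defs/rowStochasticMatrix" },
        "sizes": { "type": "array", "items": { "type": "number", "exclusiveMinimum": 0 } }
      }
    },
    "recombination": {
      "type": "array",
      "description": "partitions of 1..n with probabilities summing to 1; fraction strings such as \"2/5\" are kept exact",
      "items": {
        "type": "object",
        "required": ["partition", "prob"],
        "properties": {
          "partition": { "$ref": "#/$defs/partition" },
          "prob": { "$ref": "#/$defs/probability" }
        }
      }
    },
    "initial": {
      "type": "object",
      "description": "per-deme flat probability tables of length prod(alphabet sizes), lexicographic order with the last site varying fastest",
      "additionalProperties": { "type": "array", "items": { "type": "number", "minimum": 0 } }
    },
    "rates": {
      "type": "array",
      "description": "continuous-time recombination rates per partition (the one-block partition's rate is ignored)",
      "items": {
        "type": "object",
        "required": ["partition", "rate"],
        "properties": {
          "partition": { "$ref": "#/$defs/partition" },
          "rate": { "type": "number", "minimum": 0 }
        }
      }
    },
    "generator": {
      "type": "object",
      "description": "Markov generator on the demes: nonnegative off-diagonal entries, zero row sums"
    }
  },
  "$defs": {
    "partition": {
      "type": "array",
      "description": "blocks as arrays of site indices (bare integers are singleton blocks)",
      "items": {
        "anyOf": [
          { "type": "integer", "minimum": 1 },
          { "type": "array", "items": { "type": "integer", "minimum": 1 }, "minItems": 1 }
        ]
      },
      "minItems": 1
    },
    "probability": {
      "anyOf": [
        { "type": "number", "minimum": 0, "maximum": 1 },
        { "type": "string", "pattern": "^\\s*[0-9]+(/[0-9]+)?\\s*$" }
      ]
    },
    "rowStochasticMatrix": {
      "type": "object",
      "description": "named rows of named numeric entries; each row sums to 1"
    }
  }
}
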