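{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "trapvol contour interchange file",
  "description": "Segmented cardiac MR contours. Each contour is stored as 2D in-plane coordinates (mm) plus an explicit image-plane frame (origin + orthonormal axis_u/axis_v, mm, patient coordinates), so plane membership holds by construction. One stack per (phase, surface).",
  "type": "object",
  "required": ["schema_version", "stacks"],
  "properties": {
    "schema_version": { "const": "1.0" },
    "subject_id": { "type": "string" },
    "units": { "const": "mm" },
    "stacks": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["phase", "surface", "contours"],
        "properties": {
          "phase": { "enum": ["ED", "ES"] },
          "surface": { "enum": ["endocardium", "epicardium"] },
          "slice_thickness_mm": { "type": "number", "exclusiveMinimum": 0 },
          "gap_mm": { "type": "number", "minimum": 0 },
          "contours": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["view", "plane", "points"],
              "properties": {
                "view": { "enum": ["SAX", "LAX"] },
                "slice_index": {
                  "type": "integer",
                  "minimum": 0,
                  "description": "required for SAX records; 0 = most basal; strictly increasing within a stack"
                },
                "plane": {
                  "type": "object",
                  "required": ["origin", "axis_u", "axis_v"],
                  "properties": {
                    "origin": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 },
                    "axis_u": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 },
                    "axis_v": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 }
                  }
                },
                "points": {
                  "type": "array",
                  "minItems": 3,
                  "items": { "type": "array", "items": { "type": "number" }, "minItems": 2, "maxItems": 2 },
                  "description": "closed simple polygon, first point not repeated"
                }
              }
            }
          }
        }
      }
    }
  }
}
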