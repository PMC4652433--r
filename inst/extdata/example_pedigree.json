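{
  "schema_version": "1.0",
  "proband_note": "",
  "relatives": [
    {
      "role": "mother",
      "member_index": 0,
      "affected": true,
      "age_dx": 52,
      "multiple_polyps": false,
      "other_cancers": false,
      "multiple_crc": false
    },
    {
      "role": "maternal_grandmother",
      "member_index": 0,
      "affected": true,
      "age_dx": 49,
      "multiple_polyps": false,
      "other_cancers": false,
      "multiple_crc": false
    },
    {
      "role": "maternal_aunt_uncle",
      "member_index": 0,
      "affected": true,
      "age_dx": 47,
      "multiple_polyps": false,
      "other_cancers": false,
      "multiple_crc": false
    },
    {
      "role": "sibling",
      "member_index": 0,
      "affected": true,
      "age_dx": 61,
      "multiple_polyps": false,
      "other_cancers": true,
      "multiple_crc": false
    }
  ]
}
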