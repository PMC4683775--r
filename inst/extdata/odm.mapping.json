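{
  "name": "odm-1.3-metadata",
  "format_type": "xml",
  "root": "ODM",
  "namespace": "http://www.cdisc.org/ns/odm/v1.3",
  "tags": [
    {
      "tag": "ODM",
      "is_root": true,
      "contains": true,
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "subtags": [
        "Study"
      ]
    },
    {
      "tag": "Study",
      "is_root": false,
      "contains": true,
      "category": "Study",
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "attributes": {
        "OID": ":NAME"
      },
      "subtags": [
        "GlobalVariables",
        "MetaDataVersion"
      ]
    },
    {
      "tag": "GlobalVariables",
      "is_root": false,
      "contains": true,
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "subtags": [
        "StudyName"
      ]
    },
    {
      "tag": "StudyName",
      "is_root": false,
      "contains": true,
      "text_slot": "name",
      "ref_slot": ":NAME",
      "ref_into": "contains"
    },
    {
      "tag": "MetaDataVersion",
      "is_root": false,
      "contains": true,
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "subtags": [
        "ItemGroupDef",
        "CodeList"
      ]
    },
    {
      "tag": "ItemGroupDef",
      "is_root": false,
      "contains": true,
      "category": "Module",
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "attributes": {
        "OID": ":NAME",
        "Name": "name"
      },
      "subtags": [
        "ItemDef"
      ]
    },
    {
      "tag": "ItemDef",
      "is_root": false,
      "contains": true,
      "category": "Item",
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "attributes": {
        "OID": ":NAME",
        "Name": "name",
        "DataType": "data_type"
      },
      "subtags": [
        "Description",
        "CodeListRef"
      ]
    },
    {
      "tag": "Description",
      "is_root": false,
      "contains": true,
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "subtags": [
        "TranslatedText"
      ]
    },
    {
      "tag": "TranslatedText",
      "is_root": false,
      "contains": true,
      "text_slot": "description",
      "ref_slot": ":NAME",
      "ref_into": "contains"
    },
    {
      "tag": "CodeListRef",
      "is_root": false,
      "contains": true,
      "category": "Codelist",
      "ref_attribute": "CodeListOID",
      "ref_slot": ":NAME",
      "ref_into": "codelist"
    },
    {
      "tag": "CodeList",
      "is_root": false,
      "contains": false,
      "category": "Codelist",
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "attributes": {
        "OID": ":NAME",
        "Name": "name"
      },
      "subtags": [
        "CodeListItem"
      ]
    },
    {
      "tag": "CodeListItem",
      "is_root": false,
      "contains": true,
      "ref_slot": ":NAME",
      "ref_into": "contains",
      "attributes": {
        "CodedValue": "codes"
      }
    }
  ]
}
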