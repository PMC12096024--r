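treatment_id,name,ACR,OARSI,ESCEO,AAOS,NICE
T01,land-based exercise,SR,SR,SR,SR,SR
T02,weight management,SR,SR,SR,SR,NA
T03,topical NSAIDs,SR,SR,CR,SR,SR
T04,oral NSAIDs,CR,CR,CR,SR,CR
T05,acetaminophen,CR,CRA,CR,CR,NA
T06,intraarticular corticosteroids,CR,CR,NA,CR,CR
T07,hyaluronic acid injection,CRA,INC,CR,CRA,CRA
T08,glucosamine,SRA,SRA,CR,SRA,SRA
T09,opioids,CRA,SRA,CRA,CRA,NA
T10,arthroscopic lavage,SRA,SRA,NA,SRA,SRA
T11,acupuncture,CR,NA,NA,NA,NA
T12,TENS,CRA,CRA,NA,INC,NA
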