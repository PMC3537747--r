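# Canonical PFT report layout

Plain-text, machine-generated, one document per test. Six sections in fixed
order; LUNG VOLUMES and DIFFUSION are absent entirely when the component was
not administered. All other sections are always present. Line format is
fixed: labels at column 1, values right-aligned in 8-9 character columns
(the extraction rules anchor on labels and whitespace runs, not on absolute
column positions). Dates print as MM/DD/YYYY; decimals use a period
separator, no thousands separators.

## 1. HEADER

```
PULMONARY FUNCTION TEST REPORT
--------------------------------------------------------------------------
Name: <LAST, FIRST>
MRN: <8 digits>          Exam Date: <MM/DD/YYYY>
DOB: <MM/DD/YYYY>
Gender: <M|F>    Race: <text>    Ethnicity: <text>
Patient Type: <Inpatient|Outpatient>
Height (cm): <n.n>    Weight (kg): <n.n>
Ordering Physician: <text>
Technician: <text>
```

The MRN/exam-date line is the report's identity and is the only line the
default ruleset requires. DOB is rendered but not part of the mart
dictionary.

## 2. SPIROMETRY (always present; 9 measures x 6 numeric columns = 54 fields)

```
SPIROMETRY
                              Pre    %Pred     Post    %Pred    %Chg     LLN
FVC (L)                      n.nn      nnn     n.nn      nnn      nn       b
FEV1 (L)        ...
FEV1/FVC (%)    FEF25-75 (L/s)    PEF (L/s)    FEF50 (L/s)
FIVC (L)        FIV1 (L)          MVV (L/min)
```

Columns: pre-bronchodilator value, % predicted, post-bronchodilator value,
% predicted, % change (signed integer), below-lower-limit-of-normal flag
(0/1).

## 3. LUNG VOLUMES (optional; 13 measures x 2 columns = 26 fields)

```
LUNG VOLUMES
                            Value    %Pred
TLC (L)    VC (L)    FRC (L)    RV (L)    ERV (L)    IC (L)    RV/TLC (%)
SVC (L)    TGV (L)   Raw (cmH2O/L/s)   sGaw (1/cmH2O/s)   VTG (L)
He Equil Time (min)
```

## 4. DIFFUSION (optional; 6 measures x 2 columns = 12 fields)

```
DIFFUSION
                            Value    %Pred
DLCO (mL/min/mmHg)    DLCOcorr (mL/min/mmHg)    DL/VA (mL/min/mmHg/L)
VA (L)    IVC (L)    Hb (g/dL)
```

## 5. PULSE OXIMETRY (always present; 2 fields)

```
PULSE OXIMETRY
SpO2 Rest (%): nn
SpO2 Exertion (%): nn
```

## 6. NOTES (always present; 2 text fields)

```
NOTES
Test Quality: <A|B|C|D>
Comments: <free text>
```
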