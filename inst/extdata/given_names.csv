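name,freq
JAMES,95
JOHN,92
ROBERT,88
MICHAEL,85
DAVID,82
WILLIAM,78
RICHARD,70
THOMAS,68
CHARLES,62
DANIEL,60
MATTHEW,58
ANTHONY,52
MARK,50
STEVEN,46
ANDREW,45
PETER,44
KENNETH,40
GEORGE,38
BRIAN,36
EDWARD,34
MARY,94
PATRICIA,80
JENNIFER,78
LINDA,74
ELIZABETH,72
BARBARA,66
SUSAN,64
JESSICA,60
SARAH,58
KAREN,54
NANCY,50
LISA,48
MARGARET,46
BETTY,42
SANDRA,40
ASHLEY,38
KIMBERLY,36
EMILY,34
DONNA,32
MICHELLE,30
CAROL,28
AMANDA,26
DOROTHY,24
MELISSA,22
DEBORAH,20
STEPHANIE,18
REBECCA,17
SHARON,16
LAURA,15
CYNTHIA,14
KATHLEEN,13
HELEN,12
AMY,11
SHIRLEY,10
ANGELA,9
ANNA,8
RUTH,7
BRENDA,6
PAMELA,5
NICOLE,4
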