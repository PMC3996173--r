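name,freq
SMITH,100
JONES,92
WILLIAMS,88
BROWN,84
WILSON,80
TAYLOR,76
JOHNSON,72
WHITE,68
MARTIN,64
ANDERSON,60
THOMPSON,56
NGUYEN,54
THOMAS,52
WALKER,50
HARRIS,48
LEE,46
RYAN,44
ROBINSON,42
KELLY,40
KING,38
DAVIS,36
WRIGHT,34
EVANS,32
ROBERTS,30
GREEN,28
HALL,26
WOOD,25
JACKSON,24
CLARKE,23
PATEL,22
KHAN,21
LEWIS,20
JAMES,19
PHILLIPS,18
MASON,17
MITCHELL,16
ROSE,15
DAVIES,14
RODRIGUEZ,13
COX,12
ALEXANDER,11
GARDEN,10
CAMPBELL,9
JOHNSTON,8
MOORE,7
STEWART,6
MURRAY,5
REID,4
WATSON,3
GRAHAM,3
HAMILTON,3
SCOTT,2
HENDERSON,2
FRASER,2
FERGUSON,2
CAMERON,1
DUNCAN,1
HUGHES,1
BAKER,1
BELL,1
KENNEDY,1
MARSHALL,1
SUTHERLAND,1
WALLACE,1
BLACK,1
GRANT,1
MCDONALD,1
MACKENZIE,1
SIMPSON,1
ALLAN,1
CRAWFORD,1
WELSH,1
MILLAR,1
DICKSON,1
GIBSON,1
MUNRO,1
GORDON,1
SHAW,1
BURNS,1
DOUGLAS,1
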